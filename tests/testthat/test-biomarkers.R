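test_that("the biomarker catalog enumerates 28 metrics split 8/4/11/3/2", {
  cat28 <- biomarker_catalog()
  expect_equal(nrow(cat28), 28)
  counts <- table(cat28$category)
  expect_equal(unname(counts[c("general", "pupil", "area", "search",
                               "entropy")]), c(8, 4, 11, 3, 2),
               ignore_attr = TRUE)
  # task applicability: antisaccade-only and delayed-only metrics
  expect_equal(cat28$tasks[cat28$metric == "N_SA_Fix"], "A")
  expect_equal(cat28$tasks[cat28$metric == "N_UA_Fix"], "PA")
  expect_equal(cat28$tasks[cat28$metric == "B_Intrusive_Sac"], "D")
  expect_equal(sum(cat28$tasks == "PAD"), 16)
})

test_that("general metrics summarize events with missing-safe means", {
  fx <- make_fixations(x = c(1, 2, 3), y = c(1, 2, 3),
                       t_start = c(0, 200, 500),
                       duration = c(100, 200, 300))
  sc <- data.frame(t_start = c(100, 400), t_end = c(120, 430),
                   duration = c(20, 30), amplitude = c(5, 10),
                   mean_velocity = c(100, 300), peak_velocity = c(150, 400))
  gm <- general_metrics(fx, sc, t_total = 1000)
  expect_equal(gm$N_Fix, 3)
  expect_equal(gm$T_Fix_Avg, 200)
  expect_equal(gm$V_Sac_Avg, 200)
  expect_equal(gm$V_Sac_Peak, 400)  # max of per-saccade peaks
  expect_equal(gm$A_Sac_Avg, 7.5)
  gm0 <- general_metrics(fx[0, ], sc[0, ], 1000)
  expect_equal(gm0$N_Sac, 0)
  expect_true(is.na(gm0$V_Sac_Avg))
})

test_that("antisaccade area metrics follow the CA -> WSA -> TA sequence rules", {
  scr <- screen_config()
  spec <- trial_spec("antisaccade", 15, "right")
  aois <- build_aois(spec, scr)
  wsa_x <- 960 + eccentricity_to_px(15, scr) + 150  # stimulus side, off SA
  ta_x <- 960 - eccentricity_to_px(15, scr)
  fx <- make_fixations(x = c(960, wsa_x, ta_x), y = c(540, 540, 540),
                       t_start = c(0, 1700, 2100))
  am <- area_metrics(fx, aois, spec)
  expect_equal(am$B_WSA_Fix, 1)
  expect_equal(am$B_PSA_Fix_1st, 0)  # first post-stimulus non-CA was WSA
  expect_equal(am$B_TA_Fix, 1)
  expect_equal(am$L_TA_Fix, 2100 - 1500)
  expect_equal(am$N_SA_Fix, 0)
})

test_that("delayed-trial TA fixations split into wrong/proper periods", {
  scr <- screen_config()
  spec <- trial_spec("delayed", 15, "right")
  aois <- build_aois(spec, scr)
  ta_x <- 960 + eccentricity_to_px(15, scr)
  fx <- make_fixations(x = c(960, ta_x, ta_x), y = rep(540, 3),
                       t_start = c(0, 2000, 2600))
  am <- area_metrics(fx, aois, spec)
  expect_equal(am$N_TA_W_Fix, 1)
  expect_equal(am$N_TA_P_Fix, 1)
  expect_equal(am$N_TA_Fix, 2)
  expect_equal(am$B_TA_Fix, 1)  # proper-period hit
  expect_equal(am$L_TA_Fix, 2600 - 2500)  # latency from the auditory cue
  expect_equal(am$B_Intrusive_Sac, 0)
  # a fixation leaving CA during the enforced window is intrusive
  fx2 <- make_fixations(x = c(960, 300), y = c(540, 200), t_start = c(0, 800))
  expect_equal(area_metrics(fx2, aois, spec)$B_Intrusive_Sac, 1)
})

test_that("trials without a target fixation have no latency", {
  scr <- screen_config()
  spec <- trial_spec("prosaccade", 7, "left")
  aois <- build_aois(spec, scr)
  fx <- make_fixations(x = 960, y = 540, t_start = 0)
  am <- area_metrics(fx, aois, spec)
  expect_equal(am$B_TA_Fix, 0)
  expect_true(is.na(am$L_TA_Fix))
})

test_that("search behavior needs >=2 consecutive annulus fixations", {
  scr <- screen_config()
  spec <- trial_spec("antisaccade", 15, "right")
  aois <- build_aois(spec, scr)
  l_ta <- aois$TA[["x1"]] - aois$TA[["x0"]]
  ta_cx <- (aois$TA[["x0"]] + aois$TA[["x1"]]) / 2
  ann1 <- c(ta_cx + 1.2 * l_ta, 540)
  ann2 <- c(ta_cx, 540 - 1.2 * l_ta)
  fx <- make_fixations(x = c(ann1[1], ann2[1], ta_cx),
                       y = c(ann1[2], ann2[2], 540),
                       t_start = c(1700, 1900, 2100), duration = 150)
  sr <- detect_search(fx, aois)
  expect_equal(sr$N_Search, 1)
  expect_equal(sr$B_Search, 1)
  expect_equal(sr$T_Search, 300)  # both member fixations
  # a single annulus fixation is not a search
  sr1 <- detect_search(fx[c(1, 3), ], aois)
  expect_equal(sr1$N_Search, 0)
  # fixations inside the TA never count, however close to its center
  fx_ta <- make_fixations(x = c(ta_cx, ta_cx + 10), y = c(540, 540),
                          t_start = c(1700, 1900))
  expect_equal(detect_search(fx_ta, aois)$N_Search, 0)
  # fixations beyond 1.5 * L_TA never count
  far <- make_fixations(x = c(ta_cx, ta_cx) + 2 * l_ta, y = c(540, 541),
                        t_start = c(1700, 1900))
  expect_equal(detect_search(far, aois)$N_Search, 0)
})

test_that("gaze entropies reproduce hand-computed values", {
  scr <- screen_config()
  part <- entropy_partition("prosaccade", scr)  # 3x2 grid, 640x540 cells
  # 4 fixations over 3 cells with proportions 1/2, 1/4, 1/4
  fx <- make_fixations(x = c(100, 110, 700, 1300), y = rep(100, 4),
                       t_start = c(0, 200, 400, 600))
  ge <- gaze_entropy(fx, part)
  expect_equal(ge$SGE, 1.5, tolerance = 1e-12)
  expect_equal(ge$SGE_norm, 1.5 / log2(6), tolerance = 1e-12)
  # transitions: 1->1, 1->2, 2->3; H(row1)=1, others 0; GTE = p1 * 1 = 0.5
  expect_equal(ge$GTE, 0.5, tolerance = 1e-12)
  # all fixations in one cell: both entropies vanish
  one <- gaze_entropy(make_fixations(x = rep(10, 5), y = rep(10, 5),
                                     t_start = 1:5 * 100), part)
  expect_equal(one$SGE_norm, 0)
  expect_equal(one$GTE_norm, 0)
  # strict alternation: deterministic transitions, GTE 0 while SGE > 0
  alt <- gaze_entropy(make_fixations(x = c(100, 700, 100, 700, 100, 700),
                                     y = rep(100, 6), t_start = 1:6 * 100),
                      part, self_transitions = TRUE)
  expect_equal(alt$GTE, 0)
  expect_gt(alt$SGE, 0)
  expect_true(is.na(gaze_entropy(fx[0, ], part)$SGE_norm))
})

test_that("entropies match a naive direct-summation oracle", {
  naive_entropy <- function(areas, n) {
    p <- numeric(n)
    for (a in areas) p[a] <- p[a] + 1
    p <- p / length(areas)
    sge <- 0
    for (i in 1:n) if (p[i] > 0) sge <- sge - p[i] * log2(p[i])
    gte <- 0
    if (length(areas) > 1) {
      for (i in 1:n) {
        from_i <- which(areas[-length(areas)] == i)
        if (!length(from_i) || p[i] == 0) next
        dest <- areas[from_i + 1]
        h <- 0
        for (j in 1:n) {
          pj <- sum(dest == j) / length(dest)
          if (pj > 0) h <- h - pj * log2(pj)
        }
        gte <- gte + p[i] * h
      }
    }
    c(sge, gte)
  }
  scr <- screen_config()
  set.seed(123)
  for (i in 1:1000) {
    task <- sample(c("prosaccade", "antisaccade"), 1)
    part <- entropy_partition(task, scr)
    nf <- sample(1:15, 1)
    fx <- make_fixations(x = runif(nf, 0, 1919), y = runif(nf, 0, 1079),
                         t_start = seq_len(nf) * 100)
    got <- gaze_entropy(fx, part)
    want <- naive_entropy(partition_index(fx$x, fx$y, part), part$n_areas)
    expect_equal(got$SGE, want[1], tolerance = 1e-12)
    expect_equal(got$GTE, want[2], tolerance = 1e-12)
  }
})

test_that("entropy bounds hold and the uniform distribution attains 1", {
  scr <- screen_config()
  part <- entropy_partition("prosaccade", scr)
  centers_x <- c(320, 960, 1600, 320, 960, 1600)
  centers_y <- c(270, 270, 270, 810, 810, 810)
  uni <- gaze_entropy(make_fixations(centers_x, centers_y,
                                     t_start = 1:6 * 100), part)
  expect_equal(uni$SGE_norm, 1, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:200) {
    nf <- sample(1:30, 1)
    fx <- make_fixations(x = runif(nf, 0, 1919), y = runif(nf, 0, 1079),
                         t_start = seq_len(nf) * 50)
    ge <- gaze_entropy(fx, part)
    expect_true(ge$SGE_norm >= 0 && ge$SGE_norm <= 1)
    expect_true(ge$GTE_norm >= 0 && ge$GTE_norm <= 1)
  }
})

test_that("assembled trial biomarkers respect the task applicability mask", {
  set.seed(21)
  scr <- default_screen()
  cat28 <- biomarker_catalog()
  for (task in c("prosaccade", "antisaccade", "delayed")) {
    g <- generate_trial(phenotype_params("TD-like"),
                        trial_spec(task, 15, "right"), scr, 250)
    ev <- detect_events(g$samples, scr)
    tr <- structure(list(participant_id = "P1", trial_id = 1L,
                         spec = trial_spec(task, 15, "right"),
                         samples = g$samples, fixations = ev$fixations,
                         saccades = ev$saccades, incomplete = FALSE),
                    class = "trial_record")
    bm <- compute_trial_biomarkers(tr, scr)
    expect_length(bm, 28)
    applicable <- grepl(c(prosaccade = "P", antisaccade = "A",
                          delayed = "D")[[task]], cat28$tasks)
    inapplicable <- cat28$metric[!applicable]
    expect_true(all(is.na(unlist(bm[inapplicable]))))
    # applicable metrics are present (L_TA_Fix may be NA if uncompleted)
    must_have <- setdiff(cat28$metric[applicable], "L_TA_Fix")
    expect_false(any(is.na(unlist(bm[must_have]))))
  }
})
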