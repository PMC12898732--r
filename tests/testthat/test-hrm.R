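test_that("derivative peak detection resolves one and two melting domains", {
  cfg <- run_config()
  pk <- melting_peaks(single_domain_curve(88, config = cfg))
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$tm_c - 88), 0.02)
  expect_gt(pk$height, 0)

  two <- simulate_curve(melt_model(
    domains = data.frame(tm_c = c(80, 88), weight = c(0.5, 0.5),
                         width_c = 0.45)), cfg)
  pk2 <- melting_peaks(two)
  expect_equal(nrow(pk2), 2L)
  expect_equal(sort(round(pk2$tm_c, 1)), c(80, 88), tolerance = 0.03)

  flat <- melt_curve("flat", seq(65, 94, 0.1), rep(50, 291))
  expect_equal(nrow(melting_peaks(flat)), 0L)

  expect_error(melting_peaks(single_domain_curve(88), smooth_width_c = 0.2),
               "< 7")
})

test_that("sub-threshold peaks are suppressed and threshold scales with the max", {
  cfg <- run_config()
  mk <- function(w2) simulate_curve(melt_model(
    domains = data.frame(tm_c = c(80, 88), weight = c(w2, 1 - w2),
                         width_c = 0.45)), cfg)
  ## a minor domain well below 10% of the main peak is not reported
  pk_small <- melting_peaks(mk(0.02))
  expect_equal(nrow(pk_small), 1L)
  expect_lt(abs(pk_small$tm_c - 88), 0.02)
  ## the same domain above threshold is
  pk_big <- melting_peaks(mk(0.3))
  expect_equal(nrow(pk_big), 2L)
  ## reported peaks never fall below threshold_frac * max height
  expect_true(all(pk_big$height >= 0.10 * max(pk_big$height) - 1e-9))
})

test_that("normalization pins the windows to 100% and 0%", {
  cfg <- run_config()
  cv <- single_domain_curve(88, config = cfg)
  nc <- normalize_curve(cv, config = cfg)
  tt <- nc$temperatures
  pre <- tt >= nc$pre_window[1] & tt <= nc$pre_window[2]
  post <- tt >= nc$post_window[1] & tt <= nc$post_window[2]
  expect_lt(abs(mean(nc$values[pre]) - 100), 1e-6)
  expect_lt(abs(mean(nc$values[post])), 1e-6)
})

test_that("normalization is idempotent and affine-invariant", {
  ## idempotence on an already-normalized curve with truly flat windows
  tt <- seq(65, 94, 0.1)
  v <- 100 / (1 + exp((tt - 88) / 0.45))
  v[tt <= 86] <- 100
  v[tt >= 90] <- 0
  ideal <- melt_curve("ideal", tt, v)
  nc0 <- normalize_curve(ideal, pre_window = c(66, 67.5),
                         post_window = c(92, 93.5))
  again <- normalize_curve(nc0, pre_window = c(66, 67.5),
                           post_window = c(92, 93.5))
  expect_lt(max(abs(again$values - nc0$values)), 1e-9)

  cfg <- run_config()
  cv <- single_domain_curve(88, config = cfg)
  nc <- normalize_curve(cv, config = cfg)
  shifted <- melt_curve(cv$sample_id, cv$temperatures,
                        3 * cv$fluorescence + 50)
  nc2 <- normalize_curve(shifted, config = cfg)
  expect_equal(nc2$pre_window, nc$pre_window)
  expect_lt(max(abs(nc2$values - nc$values)), 1e-9)
})

test_that("degenerate curves are rejected during normalization", {
  rising <- melt_curve("bad", seq(65, 94, 0.1),
                       seq(5, 100, length.out = 291))
  expect_error(normalize_curve(rising, pre_window = c(66, 67.5),
                               post_window = c(92, 93.5)),
               "degenerate")
})

test_that("difference curves are zero against their own centroid", {
  cfg <- run_config()
  norms <- lapply(c(a = 87.9, b = 87.9, c = 88.5), function(tm) {
    normalize_curve(single_domain_curve(tm, config = cfg), config = cfg)
  })
  for (i in seq_along(norms)) norms[[i]]$sample_id <- names(norms)[i]
  labs <- c(a = "PG", b = "PG", c = "PN")
  diffs <- difference_curves(norms, "PG", labs)
  ## reference-group differences average to the zero vector
  ref_mat <- sapply(diffs[c("a", "b")], `[[`, "values")
  expect_lt(max(abs(rowMeans(ref_mat))), 1e-9)
  ## identical non-reference samples give identical difference curves
  norms2 <- norms; norms2$d <- norms$c; norms2$d$sample_id <- "d"
  diffs2 <- difference_curves(norms2, "PG", c(labs, d = "PN"))
  expect_equal(diffs2$c$values, diffs2$d$values)
  ## a lone reference against itself is exactly zero
  solo <- difference_curves(norms["a"], "PG", labs["a"])
  expect_lt(max(abs(solo$a$values)), 1e-12)
  expect_error(difference_curves(norms, "XX", labs), "reference label")
})

test_that("genotype calls recover truth with confidence on separated groups", {
  for (s in 1:3) {
    sim <- simulate_cohort(panax_cohort_spec(seed = s))
    truth <- setNames(sim$truth$true_label, sim$truth$sample_id)
    refs <- list(
      PG = head(sim$truth$sample_id[sim$truth$true_label == "PG"], 5),
      PN = sim$truth$sample_id[sim$truth$true_label == "PN" &
                                 sim$truth$declared_label == "PN"])
    res <- hrm_authenticate(sim$curves, refs, reference_label = "PG")
    expect_equal(res$calls$call, unname(truth[res$calls$sample_id]))
    expect_true(all(res$calls$confidence > 90))
  }
})

test_that("a reference sample identical to its centroid scores confidence 100", {
  cfg <- run_config()
  norms <- list(
    normalize_curve(single_domain_curve(87.9, config = cfg, id = "r1"),
                    config = cfg),
    normalize_curve(single_domain_curve(88.5, config = cfg, id = "r2"),
                    config = cfg))
  peaks <- list(r1 = melting_peaks(single_domain_curve(87.9, config = cfg)),
                r2 = melting_peaks(single_domain_curve(88.5, config = cfg)))
  calls <- call_genotypes(norms, peaks = peaks,
                          reference_sets = list(PG = "r1", PN = "r2"))
  expect_equal(calls$call, c("PG", "PN"))
  expect_equal(calls$confidence, c(100, 100), tolerance = 1e-9)
})

test_that("genotype calls are invariant to per-sample affine transforms", {
  sim <- simulate_cohort(panax_cohort_spec(seed = 5))
  refs <- list(
    PG = head(sim$truth$sample_id[sim$truth$true_label == "PG"], 5),
    PN = sim$truth$sample_id[sim$truth$true_label == "PN" &
                               sim$truth$declared_label == "PN"])
  base <- hrm_authenticate(sim$curves, refs, reference_label = "PG")
  set.seed(77)
  warped <- lapply(sim$curves, function(cv) {
    a <- runif(1, 0.5, 4); b <- runif(1, 0, 200)
    melt_curve(cv$sample_id, cv$temperatures, a * cv$fluorescence + b,
               declared_label = cv$declared_label)
  })
  warped_res <- hrm_authenticate(warped, refs, reference_label = "PG")
  expect_equal(warped_res$calls$call, base$calls$call)
  expect_equal(warped_res$calls$tm_c, base$calls$tm_c, tolerance = 1e-6)
})

test_that("group delta-Tm matches the generating separation", {
  cfg <- run_config()
  pg <- melting_peaks(single_domain_curve(87.9, config = cfg))
  pn <- melting_peaks(single_domain_curve(88.5, config = cfg))
  dt <- delta_tm(list(PG = pg, PN = pn))
  expect_equal(dt$delta_tm_c, 0.6, tolerance = 0.02)

  same <- delta_tm(list(A = c(85, 85.1), B = c(85, 85.1)))
  expect_equal(same$delta_tm_c, 0)

  three <- delta_tm(list(A = 85, B = 86, C = 88))
  expect_equal(nrow(three), 3L)
  expect_error(delta_tm(list(A = numeric(0), B = 85)), "empty")
})

test_that("Tm estimator is unbiased and tight across the working range", {
  cfg <- run_config()
  set.seed(2024)
  tms <- runif(200, 74, 90)
  err <- vapply(tms, function(tm) {
    cv <- single_domain_curve(tm, config = cfg, noise_sd = 0.95)
    melting_peaks(cv)$tm_c[1] - tm
  }, numeric(1))
  expect_lt(mean(abs(err)), 0.03)
  expect_lt(max(abs(err)), 0.10)
})

test_that("classification succeeds at 0.6 degC separation and degrades at 0.05", {
  run_sep <- function(dtm, seeds) {
    correct <- 0L; total <- 0L
    for (s in seeds) {
      groups <- data.frame(label = c("PG", "PN"), n = c(6, 6),
                           tm_center_c = c(87.9, 87.9 + dtm),
                           tm_jitter_sd_c = 0.05)
      sim <- simulate_cohort(cohort_spec(groups,
                                         config = run_config(seed = s)))
      refs <- list(PG = sim$truth$sample_id[1:3],
                   PN = sim$truth$sample_id[7:9])
      res <- hrm_authenticate(sim$curves, refs, reference_label = "PG")
      truth <- setNames(sim$truth$true_label, sim$truth$sample_id)
      correct <- correct + sum(res$calls$call ==
                                 truth[res$calls$sample_id])
      total <- total + nrow(res$calls)
    }
    c(correct = correct, total = total)
  }
  wide <- run_sep(0.6, 1:20)
  expect_equal(wide[["correct"]], wide[["total"]])
  narrow <- run_sep(0.05, 1:20)
  expect_lt(narrow[["correct"]], narrow[["total"]])
})

test_that("predicted-vs-observed deltas are banded correctly", {
  rep <- predicted_vs_observed(c(PG = 87.0, PN = 87.6),
                               c(PG = 88.0, PN = 87.6))
  expect_equal(rep$delta_c, c(1.0, 0.0))
  expect_equal(rep$in_dye_band, c(TRUE, FALSE))
  rep2 <- predicted_vs_observed(c(A = 90), c(A = 89))
  expect_equal(rep2$delta_c, -1)
  expect_false(rep2$in_dye_band)
  expect_error(predicted_vs_observed(c(A = 1), c(B = 1)), "label sets")
})

test_that("concordance summarizes agreement, discordance and mislabels", {
  calls <- data.frame(sample_id = sprintf("s%02d", 1:30),
                      declared = rep("PG", 30),
                      call = c(rep("PG", 29), "PN"),
                      stringsAsFactors = FALSE)
  truth <- setNames(calls$call, calls$sample_id)  # truth agrees with calls
  cc <- concordance(calls, truth)
  expect_equal(cc$percent_agreement, 100)
  expect_equal(cc$mislabeled, "s30")

  truth2 <- truth; truth2["s01"] <- "PN"
  cc2 <- concordance(calls, truth2)
  expect_equal(cc2$percent_agreement, 96.7)  # 29/30, round-half-even
  expect_equal(cc2$discordant, "s01")
  expect_error(concordance(calls, truth[-1]), "missing sample")
})

test_that("mislabeled market samples are flagged by call vs declared label", {
  sim <- simulate_cohort(panax_cohort_spec(seed = 8))
  refs <- list(
    PG = head(sim$truth$sample_id[sim$truth$true_label == "PG"], 5),
    PN = sim$truth$sample_id[sim$truth$true_label == "PN" &
                               sim$truth$declared_label == "PN"])
  res <- hrm_authenticate(sim$curves, refs, reference_label = "PG")
  cc <- concordance(res$calls,
                    setNames(sim$truth$true_label, sim$truth$sample_id))
  swapped <- sim$truth$sample_id[sim$truth$declared_label !=
                                   sim$truth$true_label]
  expect_equal(sort(cc$mislabeled), sort(swapped))
  expect_equal(length(cc$mislabeled), 4L)
})
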