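## melt_sim: synthetic melting curves, cohorts and species-pair sequences

#' Two-state melt model
#'
#' Parametric generator of one sample's fluorescence melting profile: a
#' mixture of logistic duplex-fraction domains
#' \eqn{\theta_d(T) = 1/(1+\exp((T - T_{m,d})/w_d))} blended between linear
#' pre-melt and post-melt baselines,
#' \deqn{F(T) = s[\theta(T) L_{pre}(T) + (1-\theta(T)) L_{post}(T)]}
#' so that for flat baselines the \eqn{-dF/dT} apex of each domain sits
#' exactly at its \eqn{T_m} -- matching how HRM software reads Tm off the
#' derivative peak.
#'
#' @param domains data frame with columns \code{tm_c}, \code{weight}
#'   (non-negative, summing to 1) and \code{width_c} (> 0, degC); default
#'   melt width 0.45 degC.
#' @param pre_level,post_level baseline fluorescence at the grid start
#'   (RFU); \code{pre_level > post_level}.
#' @param pre_slope,post_slope baseline slopes (RFU/degC, typically <= 0).
#' @param scale multiplicative per-sample scale factor (> 0).
#' @return a list of class \code{melt_model}.
#' @export
melt_model <- function(domains = data.frame(tm_c = 85, weight = 1,
                                            width_c = 0.45),
                       pre_level = 100, post_level = 5,
                       pre_slope = -0.3, post_slope = -0.05, scale = 1) {
  stopifnot(is.data.frame(domains), nrow(domains) >= 1L,
            all(c("tm_c", "weight", "width_c") %in% names(domains)),
            all(domains$weight >= 0), all(domains$width_c > 0),
            abs(sum(domains$weight) - 1) < 1e-9,
            pre_level > post_level, scale > 0)
  structure(list(domains = domains, pre_level = pre_level,
                 post_level = post_level, pre_slope = pre_slope,
                 post_slope = post_slope, scale = scale),
            class = "melt_model")
}

#' Simulate one melting curve
#'
#' Evaluates the [melt_model()] on the configured grid and adds i.i.d.
#' Gaussian fluorescence noise. Noise draws use the current RNG state
#' (seed with \code{set.seed} for reproducibility); rare negative
#' fluorescence deviates are clamped to zero so the melt-curve
#' non-negativity invariant always holds.
#'
#' @param model a [melt_model()].
#' @param config a [run_config()] supplying the temperature grid.
#' @param noise_sd Gaussian noise standard deviation (RFU).
#' @param sample_id,declared_label metadata for the resulting curve.
#' @return a [melt_curve()].
#' @export
simulate_curve <- function(model, config = run_config(), noise_sd = 0,
                           sample_id = "sim", declared_label = NA_character_) {
  stopifnot(inherits(model, "melt_model"), noise_sd >= 0)
  tt <- .grid_of(config)
  t0 <- tt[1]
  theta <- rowSums(vapply(seq_len(nrow(model$domains)), function(d) {
    w <- model$domains$width_c[d]
    model$domains$weight[d] / (1 + exp((tt - model$domains$tm_c[d]) / w))
  }, numeric(length(tt))))
  l_pre <- model$pre_level + model$pre_slope * (tt - t0)
  l_post <- model$post_level + model$post_slope * (tt - t0)
  f <- model$scale * (theta * l_pre + (1 - theta) * l_post)
  if (noise_sd > 0) f <- f + rnorm(length(tt), 0, noise_sd)
  f <- pmax(f, 0)
  melt_curve(sample_id, tt, f, declared_label = declared_label)
}

#' Cohort specification
#'
#' Describes a labeled cohort of simulated samples: per group a sample
#' count and either a fixed Tm center or a uniform Tm range (per-sample
#' centers drawn uniformly), plus a per-sample Gaussian Tm jitter.
#' Mislabeling entries change only the declared label of a sample, never
#' the model that generates its curve, emulating market substitution.
#'
#' @param groups data frame with columns \code{label}, \code{n}
#'   (>= 1), and either \code{tm_center_c} or both \code{tm_lo_c} and
#'   \code{tm_hi_c}; optional \code{tm_jitter_sd_c} (default 0.05 degC)
#'   and \code{width_c} (default 0.45 degC).
#' @param mislabeled optional data frame with columns
#'   \code{sample_index} (1-based index into the cohort's sample order)
#'   and \code{declared_label} (one of the group labels).
#' @param noise_sd fluorescence noise sd (RFU); the default, 0.95, is 1\%
#'   of the default 95-RFU pre/post amplitude.
#' @param scale_lnorm_sd sd of the log-normal per-sample scale factor.
#' @param config a [run_config()]; its \code{seed} seeds the cohort.
#' @return a list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(groups, mislabeled = NULL, noise_sd = 0.95,
                        scale_lnorm_sd = 0.05, config = run_config()) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1L,
            all(c("label", "n") %in% names(groups)),
            all(groups$n >= 1), noise_sd >= 0)
  if (!"tm_jitter_sd_c" %in% names(groups)) groups$tm_jitter_sd_c <- 0.05
  if (!"width_c" %in% names(groups)) groups$width_c <- 0.45
  has_center <- "tm_center_c" %in% names(groups)
  has_range <- all(c("tm_lo_c", "tm_hi_c") %in% names(groups))
  if (!has_center && !has_range)
    stop("groups need tm_center_c or tm_lo_c/tm_hi_c")
  ntot <- sum(groups$n)
  if (!is.null(mislabeled)) {
    stopifnot(all(c("sample_index", "declared_label") %in% names(mislabeled)))
    if (any(mislabeled$sample_index < 1 | mislabeled$sample_index > ntot))
      stop("mislabeled sample_index out of range 1..", ntot)
    if (!all(mislabeled$declared_label %in% groups$label))
      stop("mislabeled declared_label not among group labels")
  }
  structure(list(groups = groups, mislabeled = mislabeled,
                 noise_sd = noise_sd, scale_lnorm_sd = scale_lnorm_sd,
                 config = config),
            class = "cohort_spec")
}

#' The default Panax validation cohort
#'
#' Convenience [cohort_spec()] mirroring the validation study conditions:
#' 30 commercial samples, 24 generated from the PG melting range
#' (87.8-88.0 degC) and 6 from the PN range (88.4-88.6 degC), per-sample
#' Tm jitter sd 0.05 degC, fluorescence noise 1\% of amplitude, and 4 of
#' the PN-model samples fraudulently declared "PG".
#'
#' @param seed cohort seed.
#' @param n_pg,n_pn group sizes.
#' @param n_mislabeled how many PN-model samples are declared "PG".
#' @export
panax_cohort_spec <- function(seed = 1L, n_pg = 24L, n_pn = 6L,
                              n_mislabeled = 4L) {
  stopifnot(n_mislabeled <= n_pn)
  groups <- data.frame(label = c("PG", "PN"), n = c(n_pg, n_pn),
                       tm_lo_c = c(87.8, 88.4), tm_hi_c = c(88.0, 88.6),
                       tm_jitter_sd_c = 0.05, width_c = 0.45)
  mis <- if (n_mislabeled > 0)
    data.frame(sample_index = n_pg + n_pn - seq_len(n_mislabeled) + 1L,
               declared_label = "PG")
  cohort_spec(groups, mislabeled = mis,
              config = run_config(seed = seed))
}

#' Simulate a labeled cohort of melting curves
#'
#' Each sample draws its melt midpoint (group center or uniform within the
#' group range, plus Gaussian jitter), a log-normal scale factor, and
#' fluorescence noise from its own counter-derived RNG substream, so
#' changing one group's size never reshuffles earlier samples.
#'
#' @param spec a [cohort_spec()].
#' @return a list with \code{curves} (named list of [melt_curve()]) and
#'   \code{truth} (data frame: \code{sample_id}, \code{true_label},
#'   \code{declared_label}, \code{true_tm}, \code{scale}).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  has_range <- all(c("tm_lo_c", "tm_hi_c") %in% names(g))
  seed <- spec$config$seed
  curves <- list()
  truth <- list()
  counter <- 0L
  for (k in seq_len(nrow(g))) {
    for (i in seq_len(g$n[k])) {
      counter <- counter + 1L
      id <- sprintf("S-%02d", counter)
      set.seed(.sub_seed(seed, counter))
      center <- if (has_range && !is.na(g$tm_lo_c[k]))
        runif(1, g$tm_lo_c[k], g$tm_hi_c[k]) else g$tm_center_c[k]
      tm <- center + rnorm(1, 0, g$tm_jitter_sd_c[k])
      scale <- rlnorm(1, 0, spec$scale_lnorm_sd)
      model <- melt_model(domains = data.frame(tm_c = tm, weight = 1,
                                               width_c = g$width_c[k]),
                          scale = scale)
      curves[[id]] <- simulate_curve(model, spec$config,
                                     noise_sd = spec$noise_sd,
                                     sample_id = id,
                                     declared_label = g$label[k])
      truth[[id]] <- data.frame(sample_id = id, true_label = g$label[k],
                                declared_label = g$label[k],
                                true_tm = tm, scale = scale,
                                stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(spec$mislabeled)) {
    for (m in seq_len(nrow(spec$mislabeled))) {
      idx <- spec$mislabeled$sample_index[m]
      lab <- spec$mislabeled$declared_label[m]
      truth$declared_label[idx] <- lab
      curves[[idx]]$declared_label <- lab
    }
  }
  list(curves = curves, truth = truth)
}

#' Generate a synthetic species-pair of barcode sequences
#'
#' Species A is a random sequence at a target GC content; species B is A
#' with \code{n_snps} substitutions and (optionally) one AT-only insertion
#' of \code{indel_len} bases -- the classic pattern in which an AT-rich
#' insertion lowers one species' amplicon GC and hence its Tm. All edit
#' positions are at least 25 bp from either end.
#'
#' @param length species-A length (>= 200 bp).
#' @param n_snps number of substitutions (>= 1).
#' @param indel_len AT-only insertion length (0 disables).
#' @param gc_target species-A GC fraction.
#' @param seed RNG seed.
#' @param region region annotation for the records.
#' @return a 2-row barcode data frame (as from [read_barcode_fasta()])
#'   with species labels "PG" and "PN".
#' @export
make_species_pair_fasta <- function(length = 400, n_snps = 3L,
                                    indel_len = 12L, gc_target = 0.5,
                                    seed = 1L, region = "ITS") {
  stopifnot(length >= 200, n_snps >= 1, indel_len >= 0,
            gc_target > 0, gc_target < 1)
  margin <- 25L
  if (length - 2L * margin < n_snps + 1L)
    stop("sequence too short to place edits >= 25 bp from the ends")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  a <- sample(names(p), length, replace = TRUE, prob = p)
  interior <- (margin + 1L):(length - margin)
  snp_pos <- sort(sample(interior, n_snps))
  b <- a
  for (pos in snp_pos)
    b[pos] <- sample(setdiff(c("A", "C", "G", "T"), a[pos]), 1)
  if (indel_len > 0) {
    ins_pos <- sample(setdiff(interior, snp_pos), 1)
    ins <- sample(c("A", "T"), indel_len, replace = TRUE)
    b <- append(b, ins, after = ins_pos)
  }
  data.frame(
    id = c("spA", "spB"),
    species_label = c("PG", "PN"),
    region = region,
    sequence = c(paste(a, collapse = ""), paste(b, collapse = "")),
    stringsAsFactors = FALSE)
}
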