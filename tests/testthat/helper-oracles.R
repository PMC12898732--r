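## Independent oracles, written as literal re-derivations so they share no
## code path with the package implementation.

## --- nearest-neighbor Tm by literal per-dinucleotide summation -----------
## unified oligonucleotide dH (kcal/mol) / dS (cal/mol/K), typed afresh
.orc_dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
             CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
             GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
             TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
.orc_ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
             CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
             GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
             TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

orc_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

orc_tm <- function(s, ct = 5e-8, na = 0.05, mode = "celsius_additive") {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    key <- paste0(ch[i], ch[i + 1])
    dh <- dh + .orc_dh[[key]]
    ds <- ds + .orc_ds[[key]]
  }
  for (e in c(ch[1], ch[n])) {
    if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  self <- identical(s, orc_revcomp(s))
  if (self) ds <- ds - 1.4
  x <- if (self) 1 else 4
  ds_eff <- if (mode == "entropic") ds + 0.368 * (n - 1) * log(na) else ds
  tm <- dh * 1000 / (ds_eff + 1.987 * log(ct / x)) - 273.15
  if (mode == "celsius_additive") tm <- tm + 16.6 * log10(na)
  tm
}

## --- brute-force hairpin enumeration (cubic loops) -----------------------
orc_hairpin <- function(s, temp_c = 37) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tk <- temp_c + 273.15
  loop_pen <- function(l) c("3" = 5.6, "4" = 5.6, "5" = 5.7,
                            "6" = 5.4)[as.character(min(l, 6))]
  loop_pen_any <- function(l) if (l >= 7) 6.0 else unname(loop_pen(l))
  best <- Inf
  for (i in seq_len(n)) {
    for (s_len in 4:floor((n - 3) / 2)) {
      for (l_len in 3:(n - 2 * s_len)) {
        j <- i + s_len + l_len          # arm2 start
        if (j + s_len - 1 > n) next
        arm1 <- ch[i:(i + s_len - 1)]
        arm2 <- ch[j:(j + s_len - 1)]
        if (!all(arm2 == rev(comp[arm1]))) next
        dg <- loop_pen_any(l_len)
        for (t in seq_len(s_len - 1)) {
          key <- paste0(arm1[t], arm1[t + 1])
          dg <- dg + .orc_dh[[key]] - tk * .orc_ds[[key]] / 1000
        }
        best <- min(best, dg)
      }
    }
  }
  best
}

## --- non-affine global alignment DP (per-gap-base penalty) ---------------
orc_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    sub <- D[i, j] + ifelse(x[i] == y[j], match, mismatch)
    D[i + 1, j + 1] <- max(sub, D[i, j + 1] + gap, D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

## --- least-squares fit of a 4-taxon unrooted topology --------------------
## topology given as the pair grouped with taxon 1; returns the residual
## sum of squares of the best non-negative-free LS fit of the 5 edges
orc_quartet_rss <- function(dm, partner) {
  taxa <- rownames(dm)
  others <- setdiff(taxa, c(taxa[1], partner))
  ## edges: e1=taxa[1], e2=partner, e3=others[1], e4=others[2], e5=internal
  leaf_edge <- setNames(1:4, c(taxa[1], partner, others))
  same_side <- function(u, v)
    (u %in% c(taxa[1], partner)) == (v %in% c(taxa[1], partner))
  pairs <- t(combn(taxa, 2))
  A <- matrix(0, nrow(pairs), 5)
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1]; v <- pairs[r, 2]
    A[r, leaf_edge[u]] <- 1
    A[r, leaf_edge[v]] <- 1
    if (!same_side(u, v)) A[r, 5] <- 1
    y[r] <- dm[u, v]
  }
  fit <- lm.fit(A, y)
  sum(fit$residuals^2)
}

orc_best_quartet <- function(dm) {
  taxa <- rownames(dm)
  partners <- taxa[-1]
  rss <- vapply(partners, function(p) orc_quartet_rss(dm, p), numeric(1))
  partners[which.min(rss)]
}

## --- misc helpers --------------------------------------------------------
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

single_domain_curve <- function(tm, width = 0.45, config = run_config(),
                                noise_sd = 0, id = "sim", ...) {
  simulate_curve(melt_model(domains = data.frame(tm_c = tm, weight = 1,
                                                 width_c = width), ...),
                 config, noise_sd = noise_sd, sample_id = id)
}
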