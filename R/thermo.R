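## thermo: nearest-neighbor Tm prediction, GC content, hairpin screen

## Unified oligonucleotide nearest-neighbor set (SantaLucia 1998):
## dH in kcal/mol, dS in cal/(mol K), per 5'->3' stacked dinucleotide.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.INIT_GC <- c(dH = 0.1, dS = -2.8)   # initiation at a terminal G.C pair
.INIT_AT <- c(dH = 2.3, dS = 4.1)    # initiation at a terminal A.T pair
.SYM_DS <- -1.4                      # self-complementary symmetry correction

.GAS_R <- 1.987  # cal/(mol K)

#' Thermodynamic parameter set
#'
#' Nearest-neighbor enthalpies/entropies (unified oligonucleotide set),
#' duplex initiation and symmetry terms, and the assay conditions used in
#' duplex Tm prediction: total strand concentration \code{ct} (default
#' 50 nM) and sodium-equivalent concentration \code{na} (default 50 mM).
#'
#' Two salt-correction conventions are offered. \code{"celsius_additive"}
#' adds \eqn{16.6 \log_{10}[Na^+]} degC to the 1 M Tm (the classic additive
#' empirical correction, matching a formulation in which the sodium term is
#' an additive Celsius correction factor); \code{"entropic"} instead folds
#' the salt into the entropy as \eqn{\Delta S + 0.368 (N-1) \ln[Na^+]}.
#'
#' @param ct total strand concentration, mol/L.
#' @param na sodium-equivalent concentration, mol/L.
#' @param salt_correction_mode \code{"celsius_additive"} or \code{"entropic"}.
#' @return a list of class \code{thermo_params}.
#' @export
thermo_params <- function(ct = 5e-8, na = 0.05,
                          salt_correction_mode = c("celsius_additive",
                                                   "entropic")) {
  salt_correction_mode <- match.arg(salt_correction_mode)
  stopifnot(ct > 0, na > 0)
  structure(list(nn_dh = .NN_DH, nn_ds = .NN_DS,
                 init_gc = .INIT_GC, init_at = .INIT_AT,
                 sym_ds = .SYM_DS, R = .GAS_R,
                 ct = ct, na = na,
                 salt_correction_mode = salt_correction_mode),
            class = "thermo_params")
}

#' GC content of a DNA sequence
#'
#' Ambiguity codes contribute their expected GC fraction under a uniform
#' choice among the bases they denote (e.g. S = 1, R = 1/2, B = 2/3).
#' Alignment gaps are ignored.
#'
#' @param sequence a single DNA string.
#' @return fraction of G+C in \code{[0, 1]}.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  sequence <- .check_dna(sequence)
  sequence <- .degap(sequence)
  if (nchar(sequence) == 0L) stop("sequence is empty after removing gaps")
  gcfrac <- vapply(.IUPAC, function(b) mean(b %in% c("G", "C")), numeric(1))
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(gcfrac[ch]) / length(ch)
}

#' Nearest-neighbor duplex melting temperature
#'
#' Predicts the Tm of a perfect duplex whose one strand is \code{sequence},
#' by summing nearest-neighbor stack enthalpies/entropies plus both end
#' initiation terms (and the symmetry entropy for self-complementary
#' duplexes), then
#' \deqn{T_m = \frac{\Delta H \cdot 1000}{\Delta S + R \ln(C_T/x)} - 273.15
#'       + f([Na^+])}
#' with \eqn{x = 4} for non-self-complementary duplexes and \eqn{x = 1} for
#' self-complementary ones, and \eqn{f} the configured salt correction.
#' The model is calibrated on short oligonucleotides; applying it to
#' 100-250 bp amplicons (as barcode assays do) is a documented
#' extrapolation, and measured HRM peaks with saturating dyes typically sit
#' 0.7-1.5 degC above these predictions.
#'
#' @param sequence unambiguous A/C/G/T string, length >= 8.
#' @param params a [thermo_params()] object.
#' @return a list of class \code{tm_prediction} with \code{tm_c},
#'   \code{dH_total} (kcal/mol), \code{dS_total} (cal/(mol K)),
#'   \code{gc_fraction} and \code{length}.
#' @export
predict_tm_nn <- function(sequence, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  sequence <- .check_acgt(sequence)
  n <- nchar(sequence)
  if (n < 8L) stop("sequence too short for nearest-neighbor Tm (need >= 8 bp)")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  stacks <- paste0(ch[-n], ch[-1])
  dH <- sum(params$nn_dh[stacks])
  dS <- sum(params$nn_ds[stacks])
  for (end in ch[c(1L, n)]) {
    ini <- if (end %in% c("G", "C")) params$init_gc else params$init_at
    dH <- dH + ini[["dH"]]
    dS <- dS + ini[["dS"]]
  }
  selfcomp <- identical(sequence, reverse_complement(sequence))
  if (selfcomp) dS <- dS + params$sym_ds
  x <- if (selfcomp) 1 else 4
  dS_eff <- dS
  if (params$salt_correction_mode == "entropic")
    dS_eff <- dS_eff + 0.368 * (n - 1) * log(params$na)
  tm_k <- dH * 1000 / (dS_eff + params$R * log(params$ct / x))
  tm_c <- tm_k - 273.15
  if (params$salt_correction_mode == "celsius_additive")
    tm_c <- tm_c + 16.6 * log10(params$na)
  structure(list(tm_c = tm_c, dH_total = dH, dS_total = dS,
                 gc_fraction = gc_content(sequence), length = n),
            class = "tm_prediction")
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat(sprintf("<tm_prediction> %d bp, GC %.1f%%: Tm %.2f degC (dH %.1f kcal/mol, dS %.1f cal/mol/K)\n",
              x$length, 100 * x$gc_fraction, x$tm_c, x$dH_total, x$dS_total))
  invisible(x)
}

## hairpin loop initiation penalties (kcal/mol) by loop size;
## >= 7 nt use the last entry. Representative published loop costs; only
## the sign/flagging behavior of the screen is load-bearing.
.LOOP_DG <- c("3" = 5.6, "4" = 5.6, "5" = 5.7, "6" = 5.4)
.LOOP_DG_LONG <- 6.0

.loop_penalty <- function(l) {
  ifelse(l <= 6, .LOOP_DG[as.character(pmax(l, 3))], .LOOP_DG_LONG)
}

#' Stem-loop hairpin free-energy screen
#'
#' Exhaustively enumerates perfect reverse-complement stem-loops (stem
#' length >= 4 bp, loop >= 3 nt) in a single strand and scores each as the
#' sum of the stem's nearest-neighbor stack free energies at \code{temp_c}
#' plus a size-indexed loop initiation penalty. This is a deliberately
#' simple screen for strong secondary structure in candidate amplicons --
#' a full minimum-free-energy fold is out of scope -- and a structure is
#' flagged when its free energy drops below -2 kcal/mol.
#'
#' @param sequence unambiguous A/C/G/T string, length >= 11.
#' @param temp_c evaluation temperature (degC), default 37.
#' @param flag_threshold flag when \code{min_dG} is below this (kcal/mol).
#' @return a list of class \code{hairpin_report}: \code{min_dG} (kcal/mol,
#'   \code{Inf} when no stem exists), \code{stem_start} (1-based),
#'   \code{stem_len}, \code{loop_len}, \code{flagged}.
#' @export
hairpin_screen <- function(sequence, temp_c = 37, flag_threshold = -2.0) {
  sequence <- .check_acgt(sequence)
  n <- nchar(sequence)
  if (n < 11L) stop("sequence too short for a hairpin (need >= 11 nt)")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  t_k <- temp_c + 273.15
  stack_dg <- .NN_DH - t_k * .NN_DS / 1000
  pair_ok <- function(i, j) {
    (ch[i] == "A" & ch[j] == "T") | (ch[i] == "T" & ch[j] == "A") |
      (ch[i] == "G" & ch[j] == "C") | (ch[i] == "C" & ch[j] == "G")
  }
  best <- list(min_dG = Inf, stem_start = NA_integer_,
               stem_len = NA_integer_, loop_len = NA_integer_)
  ## pairs (i, j), i < j, grouped by anti-diagonal i + j; within one
  ## anti-diagonal consecutive pairings (i+1, j-1), ... form stem runs
  for (s2 in seq(3L, 2L * n - 1L)) {
    i0 <- max(1L, s2 - n)
    imax <- (s2 - 1L) %/% 2L
    if (imax - i0 + 1L < 4L) next
    is <- i0:imax
    js <- s2 - is
    ok <- pair_ok(is, js)
    if (sum(ok) < 4L) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 4L)) {
      idx <- starts[k]:ends[k]           # outermost -> innermost pairs
      L <- length(idx)
      ri <- is[idx]; rj <- js[idx]
      ## stack free energies between consecutive pairs, read on the 5' arm
      g <- if (L > 1L)
        stack_dg[paste0(ch[ri[-L]], ch[ri[-1L]])] else numeric(0)
      G <- c(0, cumsum(g))
      for (a in seq_len(L - 3L)) {       # outer offset into the run
        smax <- L - a + 1L
        loop0 <- rj[a] - ri[a] - 1L      # loop if stem were 1 bp at offset a
        ## stem of s pairs starting at offset a: loop = loop0 - 2*(s-1)
        s_hi <- min(smax, (loop0 - 3L) %/% 2L + 1L)
        if (s_hi < 4L) next
        ss <- 4L:s_hi
        dg <- as.numeric(G[a + ss - 1L] - G[a]) +
          as.numeric(.loop_penalty(loop0 - 2L * (ss - 1L)))
        m <- which.min(dg)
        if (dg[m] < best$min_dG) {
          best$min_dG <- dg[m]
          best$stem_start <- ri[a]
          best$stem_len <- ss[m]
          best$loop_len <- loop0 - 2L * (ss[m] - 1L)
        }
      }
    }
  }
  best$flagged <- is.finite(best$min_dG) && best$min_dG < flag_threshold
  structure(best, class = "hairpin_report")
}

#' @export
print.hairpin_report <- function(x, ...) {
  if (!is.finite(x$min_dG)) {
    cat("<hairpin_report> no stem-loop (min_dG = +Inf), not flagged\n")
  } else {
    cat(sprintf("<hairpin_report> min dG %.2f kcal/mol (stem %d bp at %d, loop %d nt)%s\n",
                x$min_dG, x$stem_len, x$stem_start, x$loop_len,
                if (x$flagged) " [FLAGGED]" else ""))
  }
  invisible(x)
}
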