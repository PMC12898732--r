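## barcode_screen: alignment, variant discovery, amplicon enumeration,
## screening/ranking rules

#' Global pairwise alignment of two barcode sequences
#'
#' Needleman-Wunsch global alignment with affine gaps. Under the scoring
#' convention used here a gap of length L contributes
#' \code{gap_open + (L-1)*gap_extend} to the score (the first gapped base
#' pays the opening). The optimal score is computed by
#' \code{Biostrings::pairwiseAlignment}; tie-breaking among co-optimal
#' paths is deterministic but implementation-defined.
#'
#' @param a,b DNA strings (unambiguous bases recommended; IUPAC codes are
#'   passed through and scored as mismatches against other letters).
#' @param a_id,b_id identifiers recorded in the result.
#' @param match,mismatch,gap_open,gap_extend scoring scheme; gap penalties
#'   must be non-positive with \code{gap_open <= gap_extend}.
#' @return a list of class \code{pairwise_alignment}: \code{seq_a_id},
#'   \code{seq_b_id}, \code{aligned_a}, \code{aligned_b} (equal-length
#'   gapped strings whose degapped forms reproduce the inputs), and
#'   \code{score}.
#' @export
align_global <- function(a, b, a_id = "A", b_id = "B",
                         match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -0.5) {
  a <- .check_dna(a, "sequence a", allow_gap = FALSE)
  b <- .check_dna(b, "sequence b", allow_gap = FALSE)
  stopifnot(gap_open <= gap_extend, gap_extend <= 0, match > mismatch)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = -(gap_open - gap_extend), gapExtension = -gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  stopifnot(identical(.degap(aligned_a), a),
            identical(.degap(aligned_b), b))
  structure(list(seq_a_id = a_id, seq_b_id = b_id,
                 aligned_a = aligned_a, aligned_b = aligned_b,
                 score = Biostrings::score(pa)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s, %d columns, score %.2f\n",
              x$seq_a_id, x$seq_b_id, nchar(x$aligned_a), x$score))
  invisible(x)
}

.iupac_compatible <- function(x, y) {
  length(intersect(.IUPAC[[x]], .IUPAC[[y]])) > 0L
}

#' Species-discriminatory variant sites of a pairwise alignment
#'
#' Substitution columns become SNP sites; maximal runs of gap-containing
#' columns merge into single InDel sites. Columns where an ambiguity code
#' in one sequence is compatible with the base in the other (shared IUPAC
#' expansion) are not variants.
#'
#' @param aln a [align_global()] result.
#' @return data frame with columns \code{column} (1-based alignment column
#'   of the site start), \code{end_column}, \code{kind} ("SNP" or
#'   "InDel"), \code{allele_a}, \code{allele_b}.
#' @export
find_variant_sites <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  gapcol <- ca == "-" | cb == "-"
  snpcol <- !gapcol & ca != cb &
    !mapply(.iupac_compatible, ca, cb)
  sites <- list()
  ## InDel: merge maximal gap-column runs
  r <- rle(gapcol)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    sites[[length(sites) + 1L]] <- data.frame(
      column = i, end_column = j, kind = "InDel",
      allele_a = paste(ca[i:j], collapse = ""),
      allele_b = paste(cb[i:j], collapse = ""),
      stringsAsFactors = FALSE)
  }
  for (i in which(snpcol)) {
    sites[[length(sites) + 1L]] <- data.frame(
      column = i, end_column = i, kind = "SNP",
      allele_a = ca[i], allele_b = cb[i], stringsAsFactors = FALSE)
  }
  if (!length(sites))
    return(data.frame(column = integer(), end_column = integer(),
                      kind = character(), allele_a = character(),
                      allele_b = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, sites)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate amplicons around variant sites
#'
#' Scans alignment windows on a stride and keeps those whose degapped
#' per-species lengths fall within \code{[min_len, max_len]}, that contain
#' at least one variant site, and whose first and last \code{flank}
#' alignment columns are variant-free (the primer-compatibility surrogate:
#' primers must bind identically in both species, and their sequences are
#' recorded as the flank substrings). Windows carrying the same variant
#' set are deduplicated keeping the shortest. Per-species GC and predicted
#' Tm are filled from the thermodynamic module.
#'
#' @param aln a [align_global()] result.
#' @param variants output of [find_variant_sites()] for \code{aln}.
#' @param min_len,max_len degapped amplicon length bounds (bp).
#' @param flank required variant-free columns at each window end.
#' @param stride window start/stop enumeration stride (columns).
#' @param params [thermo_params()] for Tm prediction.
#' @param region annotation copied into the candidates.
#' @return data frame of candidates: \code{name}, \code{region},
#'   \code{start}, \code{end} (1-based inclusive on the degapped species-A
#'   sequence), \code{amplicon_a}, \code{amplicon_b}, \code{length_a},
#'   \code{length_b}, \code{gc_a}, \code{gc_b}, \code{tm_a}, \code{tm_b},
#'   \code{n_variants}, \code{variant_kinds}, \code{primer_fwd},
#'   \code{primer_rev}. Empty (with a warning) when no window satisfies
#'   the constraints.
#' @export
enumerate_amplicons <- function(aln, variants, min_len = 100, max_len = 250,
                                flank = 20, stride = 5,
                                params = thermo_params(), region = "") {
  stopifnot(inherits(aln, "pairwise_alignment"), nrow(variants) >= 1L,
            min_len <= max_len, flank > 0, stride >= 1)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  varcol <- logical(n)
  for (v in seq_len(nrow(variants)))
    varcol[variants$column[v]:variants$end_column[v]] <- TRUE
  ## positions on degapped A for coordinate reporting
  posa <- cumsum(ca != "-")
  cand <- list()
  for (i in seq(1L, n, by = stride)) {
    for (j in seq(min(i + min_len - 1L, n), n, by = stride)) {
      if (j - i + 1L < 2L * flank + 1L) next
      la <- sum(ca[i:j] != "-")
      lb <- sum(cb[i:j] != "-")
      if (la < min_len || la > max_len || lb < min_len || lb > max_len) next
      if (any(varcol[i:(i + flank - 1L)]) ||
          any(varcol[(j - flank + 1L):j])) next
      inside <- variants$column >= i + flank &
        variants$end_column <= j - flank
      if (!any(inside)) next
      key <- paste(which(inside), collapse = ",")
      amp_a <- .degap(paste(ca[i:j], collapse = ""))
      amp_b <- .degap(paste(cb[i:j], collapse = ""))
      rec <- list(col_i = i, col_j = j,
                  start = posa[i] + (ca[i] == "-"), end = posa[j],
                  amplicon_a = amp_a, amplicon_b = amp_b,
                  length_a = la, length_b = lb,
                  n_variants = sum(inside),
                  variant_kinds = paste(sort(unique(
                    variants$kind[inside])), collapse = ","),
                  primer_fwd = .degap(paste(ca[i:(i + flank - 1L)],
                                            collapse = "")),
                  primer_rev = reverse_complement(
                    .degap(paste(ca[(j - flank + 1L):j], collapse = ""))))
      if (is.null(cand[[key]]) ||
          cand[[key]]$length_a + cand[[key]]$length_b > la + lb)
        cand[[key]] <- rec
    }
  }
  if (!length(cand)) {
    warning("no amplicon window satisfies the length/flank constraints")
    return(data.frame())
  }
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "col_i"),
                     vapply(cand, `[[`, numeric(1), "col_j"))]
  out <- do.call(rbind, lapply(cand, function(r)
    data.frame(r[setdiff(names(r), c("col_i", "col_j"))],
               stringsAsFactors = FALSE)))
  out$name <- sprintf("AMP-%03d", seq_len(nrow(out)))
  out$region <- region
  out$gc_a <- vapply(out$amplicon_a, gc_content, numeric(1), USE.NAMES = FALSE)
  out$gc_b <- vapply(out$amplicon_b, gc_content, numeric(1), USE.NAMES = FALSE)
  out$tm_a <- vapply(out$amplicon_a, function(s)
    predict_tm_nn(s, params)$tm_c, numeric(1), USE.NAMES = FALSE)
  out$tm_b <- vapply(out$amplicon_b, function(s)
    predict_tm_nn(s, params)$tm_c, numeric(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out[, c("name", "region", "start", "end", "amplicon_a", "amplicon_b",
          "length_a", "length_b", "gc_a", "gc_b", "tm_a", "tm_b",
          "n_variants", "variant_kinds", "primer_fwd", "primer_rev")]
}

#' Screen and rank candidate amplicons
#'
#' Applies the two-stage screening rules used to pick a discriminatory
#' assay: stage 1 retains candidates with a species Tm difference above
#' 0.3 degC (strict); candidates with a small difference (< 0.4 degC)
#' whose only variation is a single SNP are excluded as unreliable. The
#' survivors are ranked by
#' \code{w_dtm * min(delta_tm, cap) + w_len * [both lengths in 100-200 bp]
#' + w_gc * [both GC in 40-60\%] + w_multi * [more than one variant]},
#' which prefers a moderately separated but GC-balanced, multi-polymorphic
#' amplicon over AT-rich candidates with larger raw separation. Ties break
#' to the shorter amplicon, then the lexicographically smallest name.
#'
#' @param cands data frame from [enumerate_amplicons()] (needs columns
#'   \code{name}, \code{length_a}, \code{length_b}, \code{gc_a},
#'   \code{gc_b}, \code{n_variants}, \code{variant_kinds}, and
#'   \code{tm_a}/\code{tm_b} when \code{delta_tm} is not given).
#' @param delta_tm per-candidate Tm difference (degC); defaults to
#'   \code{|tm_a - tm_b|} from the predictions ("design mode"); pass
#'   measured peak differences for "assay mode".
#' @param delta_tm_source recorded provenance of \code{delta_tm}.
#' @param weights named numeric: \code{dtm}, \code{len}, \code{gc},
#'   \code{multi}.
#' @param dtm_cap cap on the delta-Tm term (degC).
#' @return data frame of class \code{screen_report} with per-candidate
#'   \code{delta_tm}, \code{pass_stage1}, \code{excluded_single_snp},
#'   \code{retained}, \code{in_optimal_window}, \code{rank_score},
#'   \code{nominated}; the nominee's name is in
#'   \code{attr(, "nominated")}.
#' @export
screen_candidates <- function(cands, delta_tm = NULL,
                              delta_tm_source = c("predicted", "measured"),
                              weights = c(dtm = 1.0, len = 0.5,
                                          gc = 0.5, multi = 0.5),
                              dtm_cap = 1.5) {
  delta_tm_source <- match.arg(delta_tm_source)
  if (!is.data.frame(cands) || nrow(cands) == 0L)
    stop("empty candidate list")
  stopifnot(all(c("dtm", "len", "gc", "multi") %in% names(weights)))
  if (is.null(delta_tm)) delta_tm <- abs(cands$tm_a - cands$tm_b)
  stopifnot(length(delta_tm) == nrow(cands))
  pass_stage1 <- delta_tm > 0.3
  excluded_single_snp <- delta_tm < 0.4 & cands$n_variants == 1L &
    cands$variant_kinds == "SNP"
  retained <- pass_stage1 & !excluded_single_snp
  len_ok <- cands$length_a >= 100 & cands$length_a <= 200 &
    cands$length_b >= 100 & cands$length_b <= 200
  gc_ok <- cands$gc_a >= 0.40 & cands$gc_a <= 0.60 &
    cands$gc_b >= 0.40 & cands$gc_b <= 0.60
  in_optimal_window <- len_ok & gc_ok
  rank_score <- weights[["dtm"]] * pmin(delta_tm, dtm_cap) +
    weights[["len"]] * len_ok + weights[["gc"]] * gc_ok +
    weights[["multi"]] * (cands$n_variants > 1L)
  rep <- data.frame(name = cands$name, delta_tm = delta_tm,
                    delta_tm_source = delta_tm_source,
                    pass_stage1 = pass_stage1,
                    excluded_single_snp = excluded_single_snp,
                    retained = retained,
                    in_optimal_window = in_optimal_window,
                    rank_score = rank_score,
                    stringsAsFactors = FALSE)
  nominated <- NA_character_
  if (any(retained)) {
    cl <- rep[retained, , drop = FALSE]
    mean_len <- (cands$length_a + cands$length_b)[retained] / 2
    ord <- order(-cl$rank_score, mean_len, cl$name)
    nominated <- cl$name[ord[1]]
  }
  rep$nominated <- rep$name == nominated & !is.na(nominated)
  attr(rep, "nominated") <- nominated
  class(rep) <- c("screen_report", "data.frame")
  rep
}
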