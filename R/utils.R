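## shared internal helpers

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.DNA_CHARS <- c(names(.IUPAC), "-")

.check_dna <- function(x, what = "sequence", allow_gap = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (nchar(x) == 0L) stop(what, " is empty")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  ok <- .DNA_CHARS
  if (!allow_gap) ok <- setdiff(ok, "-")
  bad <- setdiff(unique(ch), ok)
  if (length(bad))
    stop(what, " contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  x
}

.check_acgt <- function(x, what = "sequence") {
  x <- .check_dna(x, what, allow_gap = FALSE)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  amb <- setdiff(unique(ch), c("A", "C", "G", "T"))
  if (length(amb))
    stop(what, " contains ambiguity codes (", paste(amb, collapse = ", "),
         "); resolve variants into concrete per-species sequences first")
  x
}

#' Reverse complement of a DNA sequence
#'
#' @param x a single DNA string (IUPAC codes and gaps allowed; ambiguity
#'   codes are complemented through their IUPAC complements).
#' @return the reverse complement, upper case.
#' @examples
#' reverse_complement("ACGT")
#' @export
reverse_complement <- function(x) {
  x <- .check_dna(x, allow_gap = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N", "-" = "-")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[ch])), collapse = "")
}

.degap <- function(x) gsub("-", "", x, fixed = TRUE)

## deterministic 32-bit-safe sub-seed for per-sample RNG substreams
.sub_seed <- function(seed, counter) {
  v <- ((as.numeric(seed) %% 2147483563) * 40014 + counter * 40692) %%
    2147483563
  as.integer(v %% 2147483562) + 1L
}

.round1 <- function(x) round(x, 1)  # base round: IEC 60559 round-half-even
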