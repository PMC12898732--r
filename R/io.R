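## io_and_formats: FASTA / melt CSV / label TSV / Newick / run configuration

#' Melt-curve container
#'
#' One sample's fluorescence-versus-temperature trace on a constant grid,
#' the unit of data the HRM stage consumes.
#'
#' @param sample_id sample identifier.
#' @param temperatures strictly increasing, constant-spacing grid (degrees
#'   Celsius, within \code{[0, 120]}, at least 20 points; spacing constant
#'   within 1e-9).
#' @param fluorescence non-negative relative fluorescence units, same length.
#' @param declared_label optional label under which the sample is sold or
#'   claimed (used for mislabel detection, never for calling).
#' @return an object of class \code{melt_curve}.
#' @export
melt_curve <- function(sample_id, temperatures, fluorescence,
                       declared_label = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  n <- length(temperatures)
  if (n < 20L)
    stop("melt curve '", sample_id, "': need >= 20 grid points, got ", n)
  if (length(fluorescence) != n)
    stop("melt curve '", sample_id, "': temperature/fluorescence length mismatch")
  if (any(temperatures < 0) || any(temperatures > 120))
    stop("melt curve '", sample_id, "': temperatures outside [0, 120] degC")
  dt <- diff(temperatures)
  if (any(dt <= 0))
    stop("melt curve '", sample_id, "': temperatures not strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop("melt curve '", sample_id, "': non-constant temperature grid ",
         "(max spacing deviation ", format(max(dt) - min(dt)), " degC)")
  if (any(fluorescence < 0))
    stop("melt curve '", sample_id, "': negative fluorescence")
  structure(list(sample_id = sample_id,
                 declared_label = declared_label,
                 temperatures = temperatures,
                 fluorescence = fluorescence),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s  [%g..%g degC x %d, step %.4g]%s\n",
              x$sample_id, min(x$temperatures), max(x$temperatures),
              length(x$temperatures), diff(x$temperatures[1:2]),
              if (is.na(x$declared_label)) ""
              else paste0("  declared=", x$declared_label)))
  invisible(x)
}

#' Read species-labeled barcode sequences from a FASTA file
#'
#' Headers may carry \code{species=...;region=...;} key=value tokens after
#' the identifier; absent tokens leave the field empty. The first
#' whitespace-delimited token is the record id.
#'
#' @param path FASTA file.
#' @return a data frame with columns \code{id}, \code{species_label},
#'   \code{region}, \code{sequence} (upper-case IUPAC DNA).
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(), species_label = character(),
                      region = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L)
    return(data.frame(id = character(), species_label = character(),
                      region = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  if (!startsWith(nonblank[1], ">"))
    stop("malformed FASTA in ", path, ": line ",
         which(nzchar(trimws(lines)))[1], " does not start with '>'")
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tok <- function(h, key) {
    m <- regmatches(h, regexec(paste0(key, "=([^;\\s]+)"), h))[[1]]
    if (length(m) == 2L) m[2] else ""
  }
  out <- data.frame(
    id = ids,
    species_label = vapply(headers, tok, character(1), key = "species",
                           USE.NAMES = FALSE),
    region = vapply(headers, tok, character(1), key = "region",
                    USE.NAMES = FALSE),
    sequence = toupper(as.character(set)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (i in seq_len(nrow(out)))
    .check_dna(out$sequence[i], paste0("record '", out$id[i], "'"))
  out
}

#' Write barcode records to FASTA
#'
#' @param records data frame as returned by [read_barcode_fasta()].
#' @param path output file.
#' @export
write_barcode_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  hdr <- records$id
  sp <- if ("species_label" %in% names(records)) records$species_label else ""
  rg <- if ("region" %in% names(records)) records$region else ""
  extra <- paste0(ifelse(nzchar(sp), paste0("species=", sp, ";"), ""),
                  ifelse(nzchar(rg), paste0("region=", rg, ";"), ""))
  hdr <- ifelse(nzchar(extra), paste(hdr, extra), hdr)
  writeLines(paste0(">", hdr, "\n", records$sequence), path)
  invisible(path)
}

#' Read melting curves from a long-format CSV
#'
#' Expected columns: \code{sample_id}, \code{temperature_c},
#' \code{fluorescence}, optionally \code{declared_label}. Rows may appear in
#' any order; each sample's rows are sorted by temperature and validated
#' against the constant-grid invariant.
#'
#' @param path CSV file.
#' @return a named list of [melt_curve()] objects (one per sample, in first
#'   order of appearance).
#' @export
read_melt_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "temperature_c", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("melt CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    g <- df[df$sample_id == id, , drop = FALSE]
    g <- g[order(g$temperature_c), , drop = FALSE]
    if (anyDuplicated(g$temperature_c))
      stop("melt CSV ", path, ": duplicated (sample, temperature) rows for ",
           "sample '", id, "'")
    lab <- if ("declared_label" %in% names(g)) as.character(g$declared_label[1])
           else NA_character_
    melt_curve(as.character(id), g$temperature_c, g$fluorescence,
               declared_label = lab)
  })
  names(out) <- ids
  out
}

#' Write melting curves to a long-format CSV
#'
#' @param curves a list of [melt_curve()] objects.
#' @param path output CSV file.
#' @export
write_melt_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id,
               temperature_c = cv$temperatures,
               fluorescence = cv$fluorescence,
               declared_label = cv$declared_label,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$declared_label))) df$declared_label <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sample label tables
#'
#' Two-column TSV \code{sample_id <TAB> label}, used for reference sets and
#' truth tables.
#'
#' @param path TSV file.
#' @return named character vector, names = sample ids.
#' @export
read_labels_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label TSV needs at least two columns")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_labels_tsv
#' @param labels named character vector (names = sample ids).
#' @export
write_labels_tsv <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), label = unname(labels))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are required and must be non-negative (negative
#' neighbor-joining branches are expected to have been clamped by
#' [nj_tree()]); integer bootstrap supports present as node labels are
#' carried through. The written file round-trips through [read_newick()].
#'
#' @param tree an \code{ape::phylo} tree, or a single character tip label
#'   for the degenerate one-taxon case.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  if (is.character(tree) && length(tree) == 1L) {
    writeLines(paste0(tree, ";"), path)
    return(invisible(path))
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) after clamping policy; refusing to write")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Run configuration
#'
#' Bundles the acquisition grid and the analysis defaults shared by the
#' simulator and the HRM pipeline. Defaults mirror a 65–94 degC ramp read
#' at 0.1 degC resolution and the standard amplicon assay conditions
#' (50 nM total strand concentration, 50 mM sodium).
#'
#' @param grid_start,grid_stop,grid_step temperature grid (degC).
#' @param smooth_width_c derivative smoothing half-width (degC); the local
#'   quadratic fit window spans \code{2*round(smooth_width_c/grid_step)+1}
#'   points.
#' @param threshold_frac peak threshold as a fraction of the tallest
#'   derivative peak.
#' @param window_mode \code{"auto"} places the normalization windows from
#'   the derivative; \code{"manual"} requires explicit windows.
#' @param window_width_c width of each auto-placed normalization window.
#' @param ct total strand concentration (mol/L) for Tm prediction.
#' @param na sodium-equivalent concentration (mol/L).
#' @param salt_mode \code{"celsius_additive"} or \code{"entropic"}.
#' @param seed RNG seed for simulation.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(grid_start = 65, grid_stop = 94, grid_step = 0.1,
                       smooth_width_c = 0.5, threshold_frac = 0.10,
                       window_mode = c("auto", "manual"),
                       window_width_c = 1.5,
                       ct = 5e-8, na = 0.05,
                       salt_mode = c("celsius_additive", "entropic"),
                       seed = 1L) {
  window_mode <- match.arg(window_mode)
  salt_mode <- match.arg(salt_mode)
  stopifnot(grid_start < grid_stop, grid_step > 0,
            smooth_width_c > 0, window_width_c > 0,
            threshold_frac >= 0, threshold_frac < 1,
            ct > 0, na > 0)
  structure(list(grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step, smooth_width_c = smooth_width_c,
                 threshold_frac = threshold_frac, window_mode = window_mode,
                 window_width_c = window_width_c, ct = ct, na = na,
                 salt_mode = salt_mode, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path an INI-style \code{key = value} file (\code{#} or \code{;}
#'   comments and \code{[section]} headers are ignored); keys match the
#'   arguments of \code{run_config} and override its defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("cannot parse config line: ", lines[bad][1])
  vals <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.grid_of <- function(config) {
  seq(config$grid_start, config$grid_stop, by = config$grid_step)
}
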