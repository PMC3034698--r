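#' Column-name dialect for genetic-map files
#'
#' Map files from different tools name their columns differently; the dialect
#' maps the canonical field names onto the header names actually present.
#'
#' @param id,lg,pos,mclass,distortion_p header names for the marker id,
#'   linkage-group label, cM position, marker class and distortion p-value.
#' @return named character vector usable as the `dialect` argument of
#'   [read_genetic_map()].
#' @export
map_dialect <- function(id = "marker", lg = "lg", pos = "pos",
                        mclass = "mclass", distortion_p = "distortion_p") {
  c(id = id, lg = lg, pos = pos, mclass = mclass, distortion_p = distortion_p)
}

# number formatting shared by all writers: full precision, plain notation
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

read_tsv_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE)
}

# parse a numeric column, reporting 1-based file line numbers on failure
parse_num <- function(x, col, allow_na = FALSE) {
  x[x == "NA"] <- NA
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (!allow_na) bad <- bad | is.na(x)
  if (any(bad)) {
    stop(sprintf("non-numeric value in column '%s' at file line %d: '%s'",
                 col, which(bad)[1] + 1L, x[which(bad)[1]]))
  }
  v
}

#' Read a genetic map from TSV
#'
#' Expects a UTF-8 tab-separated file with a header, `.` decimal separator and
#' `NA` as the only missing token. The map is canonicalised on load: markers
#' sorted by (LG, position), positions normalised so each LG starts at 0, LG
#' order taken from first appearance in the file.
#'
#' @param path file path.
#' @param dialect column-name mapping, see [map_dialect()].
#' @param name map name; defaults to the file name.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, dialect = map_dialect(), name = NULL) {
  tab <- read_tsv_chr(path)
  need <- dialect[c("id", "lg", "pos")]
  miss <- setdiff(unname(need), names(tab))
  if (length(miss)) {
    stop("map file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  pos <- parse_num(tab[[dialect[["pos"]]]], dialect[["pos"]])
  if (any(pos < 0)) {
    stop(sprintf("negative position at file line %d", which(pos < 0)[1] + 1L))
  }
  df <- data.frame(marker = tab[[dialect[["id"]]]],
                   lg = tab[[dialect[["lg"]]]],
                   pos = pos,
                   stringsAsFactors = FALSE)
  if (dialect[["mclass"]] %in% names(tab)) df$mclass <- tab[[dialect[["mclass"]]]]
  if (dialect[["distortion_p"]] %in% names(tab)) {
    df$distortion_p <- parse_num(tab[[dialect[["distortion_p"]]]],
                                 dialect[["distortion_p"]], allow_na = TRUE)
  }
  genetic_map(df, name = if (is.null(name)) basename(path) else name)
}

#' Write a genetic map to canonical TSV
#'
#' Writing then re-reading is the identity on canonical-form maps (byte-stable
#' round trip).
#'
#' @param map a `genetic_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  m <- map$markers
  lines <- c(paste(c("marker", "lg", "pos", "mclass", "distortion_p"),
                   collapse = "\t"),
             paste(m$marker, m$lg, fmt_num(m$pos), m$mclass,
                   fmt_num(m$distortion_p), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a haploid genotype matrix from TSV
#'
#' First column holds individual ids, the remaining header cells are marker
#' ids; calls are `0`, `1` or `NA`.
#'
#' @param path file path.
#' @return integer matrix (individuals x markers) with `NA` for missing calls;
#'   row names are individual ids, column names marker ids.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("genotype file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  lens <- lengths(cells)
  if (any(lens != width)) {
    stop(sprintf("ragged genotype file: row %d has %d fields, expected %d",
                 which(lens != width)[1] - 1L, lens[lens != width][1], width))
  }
  header <- cells[[1L]]
  markers <- header[-1L]
  dup <- unique(markers[duplicated(markers)])
  if (length(dup)) stop("duplicate marker id(s) in header: ", paste(dup, collapse = ", "))
  body <- cells[-1L]
  inds <- vapply(body, `[[`, character(1), 1L)
  flat <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  bad <- !flat %in% c("0", "1", "NA")
  if (any(bad)) {
    stop("disallowed genotype symbol '", flat[bad][1],
         "'; allowed alphabet is {0, 1, NA}")
  }
  g <- matrix(suppressWarnings(as.integer(flat)), nrow = length(body),
              byrow = TRUE, dimnames = list(inds, markers))
  empty <- colSums(!is.na(g)) == 0L
  if (any(empty)) {
    stop("marker(s) without any non-missing call: ",
         paste(markers[empty], collapse = ", "))
  }
  g
}

#' Write a haploid genotype matrix to TSV
#' @param g integer matrix as returned by [read_genotypes()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(is.matrix(g), !is.null(colnames(g)))
  if (is.null(rownames(g))) rownames(g) <- sprintf("I%04d", seq_len(nrow(g)))
  cells <- matrix(as.character(g), nrow = nrow(g))
  cells[is.na(cells)] <- "NA"
  lines <- c(paste(c("individual", colnames(g)), collapse = "\t"),
             paste(rownames(g), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a homology-hit table from TSV
#'
#' One row per query marker: its unique best alignment to a location in the
#' target genome. Hits must be pre-deduplicated; the target LG `"Un"` denotes
#' an unassigned target sequence and may carry an absent (`NA`) position.
#'
#' @param path file path with columns `marker_id`, `target_lg`, `target_pos`,
#'   `align_len`, `score`, `identity` and optionally `annotation`.
#' @return data frame of hits.
#' @export
read_homology_hits <- function(path) {
  tab <- read_tsv_chr(path)
  need <- c("marker_id", "target_lg", "target_pos", "align_len", "score", "identity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("hit file lacks column(s): ", paste(miss, collapse = ", "))
  dup <- unique(tab$marker_id[duplicated(tab$marker_id)])
  if (length(dup)) {
    stop("multiple hits for marker(s) ", paste(dup, collapse = ", "),
         "; hits must be deduplicated to unique best hits")
  }
  hits <- data.frame(
    marker_id = tab$marker_id,
    target_lg = tab$target_lg,
    target_pos = parse_num(tab$target_pos, "target_pos", allow_na = TRUE),
    align_len = parse_num(tab$align_len, "align_len"),
    score = parse_num(tab$score, "score"),
    identity = parse_num(tab$identity, "identity"),
    annotation = if ("annotation" %in% names(tab)) tab$annotation else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  if (any(hits$align_len < 0)) stop("align_len must be >= 0")
  if (any(hits$identity < 0 | hits$identity > 100)) stop("identity must lie in [0, 100]")
  unassigned <- hits$target_lg == "Un"
  if (any(!unassigned & is.na(hits$target_pos))) {
    stop("target_pos absent for assigned-target hit(s): ",
         paste(hits$marker_id[!unassigned & is.na(hits$target_pos)], collapse = ", "))
  }
  invisible(hits)
}

#' Write a homology-hit table to TSV
#' @param hits data frame as returned by [read_homology_hits()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_homology_hits <- function(hits, path) {
  lines <- c(paste(c("marker_id", "target_lg", "target_pos", "align_len",
                     "score", "identity", "annotation"), collapse = "\t"),
             paste(hits$marker_id, hits$target_lg, fmt_num(hits$target_pos),
                   fmt_num(hits$align_len), fmt_num(hits$score),
                   fmt_num(hits$identity),
                   ifelse(is.na(hits$annotation), "NA", hits$annotation),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

round2 <- function(x) ifelse(is.na(x), NA_real_, round(x, 2))

write_plain_tsv <- function(df, path) {
  cells <- vapply(seq_along(df), function(j) {
    col <- df[[j]]
    if (is.numeric(col)) fmt_num(round2(col)) else {
      out <- as.character(col); out[is.na(out)] <- "NA"; out
    }
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write the standard report tables
#'
#' Writes TSV reports mirroring the package's three summary layouts:
#' `map_summary.tsv` (per-LG lengths, marker counts, corrected lengths with a
#' `SUM/MEAN` totals row), `lg_contingency.tsv` (query-LG x target-LG marker
#' counts) and `comparison_summary.tsv` (per-LG synteny/rearrangement spans and
#' percentages). Numbers are rounded to 2 decimals at write time only; output
#' bytes are deterministic for fixed input.
#'
#' @param summaries named list with any of the components `map_summary`
#'   (a [summarize_map()] result), `contingency` (a [build_contingency()]
#'   result) and `comparison` (a [summarize_comparison()] result).
#' @param path output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_report_tables <- function(summaries, path) {
  stopifnot(is.list(summaries))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stop("cannot create output directory: ", path)
  }
  written <- character(0)
  if (!is.null(summaries$map_summary)) {
    f <- file.path(path, "map_summary.tsv")
    write_plain_tsv(as.data.frame(summaries$map_summary), f)
    written <- c(written, f)
  }
  if (!is.null(summaries$contingency)) {
    ct <- summaries$contingency
    df <- data.frame(lg = rownames(ct), as.data.frame.matrix(ct),
                     check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(path, "lg_contingency.tsv")
    write_plain_tsv(df, f)
    written <- c(written, f)
  }
  if (!is.null(summaries$comparison)) {
    f <- file.path(path, "comparison_summary.tsv")
    write_plain_tsv(as.data.frame(summaries$comparison), f)
    written <- c(written, f)
  }
  invisible(written)
}
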