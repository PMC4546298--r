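# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinate convention: 0-based half-open, BED-native. GFF-like
# annotation (1-based inclusive) is converted on read and on write.

#' Read and write FASTA sequence files
#'
#' Sequences are returned as a named character vector, uppercased; `N` is
#' allowed. `write_fasta()` is the inverse; a read/write round trip is the
#' identity.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA headers in %s: %s", path,
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  setNames(toupper(as.character(set)), nm)
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), length(names(sequences)) > 0L)
  set <- Biostrings::DNAStringSet(toupper(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# split lines of a whitespace/TSV table, erroring with the 1-based line
# number on a column-count mismatch
parse_columns <- function(path, n_min, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) < n_min)
  if (length(bad)) {
    abort(sprintf("malformed %s line %d in %s: expected >= %d fields",
                  what, bad[1], path, n_min))
  }
  fields
}

#' Read and write analysis regions as BED6
#'
#' BED6 with 0-based half-open coordinates. The name field carries the TF
#' identifier, optionally suffixed with `_bound` / `_unbound` to carry the
#' class label; the score field carries the probe signal. Strand is
#' ignored (regions are unstranded).
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end`, `tf`, `label`
#'   (`"bound"`, `"unbound"` or `NA`) and `signal`.
#' @export
read_regions <- function(path) {
  fields <- parse_columns(path, 3L, "BED")
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s: bad coordinates",
                  bad[1], path))
  }
  name <- get(4)
  label <- dplyr::case_when(
    grepl("_bound$", name) ~ "bound",
    grepl("_unbound$", name) ~ "unbound",
    .default = NA_character_
  )
  tibble(
    chrom = get(1),
    start = as.integer(start),
    end = as.integer(end),
    tf = sub("_(un)?bound$", "", name),
    label = label,
    signal = suppressWarnings(as.numeric(get(5)))
  )
}

#' @rdname read_regions
#' @param regions Region tibble as returned by `read_regions()`.
#' @export
write_regions <- function(regions, path) {
  name <- regions$tf
  has_label <- !is.na(regions$label %||% rep(NA, nrow(regions)))
  name[has_label] <- paste0(name[has_label], "_", regions$label[has_label])
  out <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = ifelse(is.na(name), ".", name),
    score = ifelse(is.na(regions$signal), 0, regions$signal),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write a chromatin signal track (bedGraph)
#'
#' One track per chromatin-state feature; intervals are 0-based half-open
#' probe extents with one signal value each, already on the H3-normalized
#' scale when produced by the synthetic generator.
#'
#' @param path File path.
#' @param feature Feature name to attach to the track (bedGraph itself
#'   does not carry one).
#' @return A tibble with columns `feature`, `chrom`, `start`, `end`,
#'   `value`.
#' @export
read_track <- function(path, feature) {
  fields <- parse_columns(path, 4L, "bedGraph")
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4)))
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(val) | !is.finite(val) | is.na(start) | is.na(end) |
                 start < 0 | end < start)
  if (length(bad)) {
    abort(sprintf("malformed bedGraph line %d in %s", bad[1], path))
  }
  tibble(
    feature = feature,
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(start), end = as.integer(end), value = val
  )
}

#' @rdname read_track
#' @param track Track tibble.
#' @export
write_track <- function(track, path) {
  readr::write_tsv(track[c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Position weight matrices
#'
#' A PWM is stored as an `L x 4` matrix of per-position base probabilities
#' with columns `A`, `C`, `G`, `T`. The file dialect is four
#' whitespace-separated rows in `A`, `C`, `G`, `T` order with one column
#' per motif position. Positions (file columns) whose probabilities do not
#' sum to 1 within `1e-6` are renormalized with a warning, so count
#' matrices are accepted.
#'
#' @param path File path.
#' @param tf TF identifier to attach; defaults to the file base name.
#' @return An object of class `pwm_record`: list with elements `tf` and
#'   `matrix` (`L x 4`, rows summing to 1).
#' @export
read_pwm <- function(path, tf = NULL) {
  fields <- parse_columns(path, 1L, "PWM")
  fields <- lapply(fields, function(f) f[!f %in% c("A:", "C:", "G:", "T:")])
  if (length(fields) != 4L) {
    abort(sprintf("PWM file %s must have exactly 4 rows (A, C, G, T), got %d",
                  path, length(fields)))
  }
  if (length(unique(lengths(fields))) != 1L) {
    abort(sprintf("PWM rows in %s have unequal lengths", path))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), nrow = 4L,
              byrow = TRUE)
  if (anyNA(m)) abort(sprintf("non-numeric PWM entry in %s", path))
  pwm_record(t(m), tf = tf %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_pwm
#' @param matrix `L x 4` numeric matrix (or anything coercible) of
#'   per-position probabilities or counts, columns in `A,C,G,T` order.
#' @export
pwm_record <- function(matrix, tf = "TF") {
  m <- as.matrix(matrix)
  if (ncol(m) != 4L || nrow(m) < 1L) abort("PWM must be an L x 4 matrix, L >= 1")
  if (any(m < 0) || anyNA(m)) abort("PWM entries must be non-negative numbers")
  sums <- rowSums(m)
  if (any(sums == 0)) abort("PWM position with all-zero probabilities")
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    warn(sprintf("renormalizing %d PWM position(s) not summing to 1", sum(off)))
  }
  m <- m / sums
  dimnames(m) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(tf = tf, matrix = m), class = "pwm_record")
}

#' @export
print.pwm_record <- function(x, ...) {
  cat(sprintf("<pwm_record> %s, %d positions\n", x$tf, nrow(x$matrix)))
  print(round(t(x$matrix), 3))
  invisible(x)
}

#' @rdname read_pwm
#' @param pwm A `pwm_record`.
#' @export
write_pwm <- function(pwm, path) {
  writeLines(apply(t(pwm$matrix), 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read and write an expression time course
#'
#' TSV with a `gene` column and one column per time point (header row
#' gives the time labels).
#'
#' @param path File path.
#' @return Tibble with a `gene` column and numeric time-point columns.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  x
}

#' @rdname read_expression
#' @param expression Expression tibble.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

# gene-by-time numeric matrix from the tidy expression table
expression_matrix <- function(expression) {
  m <- as.matrix(expression[setdiff(names(expression), "gene")])
  rownames(m) <- expression$gene
  storage.mode(m) <- "double"
  m
}

#' Read and write a dinucleotide property table
#'
#' TSV with a `dinucleotide` column holding the 16 2-mers and one numeric
#' column per physical property (DiProDB-style). Property columns with any
#' missing value are dropped with a warning on read.
#'
#' @param path File path.
#' @return Tibble with `dinucleotide` plus numeric property columns, rows
#'   ordered `AA, AC, ..., TT`.
#' @export
read_dinuc_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "dinucleotide"
  if (nrow(x) != 16L || !setequal(x$dinucleotide, DINUCLEOTIDES)) {
    abort("dinucleotide table must have exactly the 16 dinucleotides as rows")
  }
  props <- setdiff(names(x), "dinucleotide")
  has_na <- props[vapply(x[props], anyNA, logical(1))]
  if (length(has_na)) {
    warn(sprintf("dropping %d property column(s) with missing values",
                 length(has_na)))
    x <- x[setdiff(names(x), has_na)]
  }
  x[match(DINUCLEOTIDES, x$dinucleotide), ]
}

#' @rdname read_dinuc_table
#' @param table Dinucleotide property tibble.
#' @export
write_dinuc_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read and write gene annotation (GFF3-like)
#'
#' A minimal GFF3 dialect: `gene` feature lines whose attribute column
#' carries `ID=<gene>`. GFF coordinates are 1-based inclusive and are
#' converted to the package's 0-based half-open convention on read; the
#' TSS is the strand-aware 5' end.
#'
#' @param path File path.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss` (0-based position of the transcription
#'   start site).
#' @export
read_annotation <- function(path) {
  fields <- parse_columns(path, 9L, "GFF")
  keep <- vapply(fields, function(f) f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (!length(fields)) abort(sprintf("no gene features in %s", path))
  start1 <- as.numeric(vapply(fields, `[`, character(1), 4))
  end1 <- as.numeric(vapply(fields, `[`, character(1), 5))
  strand <- vapply(fields, `[`, character(1), 7)
  attr9 <- vapply(fields, `[`, character(1), 9)
  gene <- sub("^.*ID=([^;]+).*$", "\\1", attr9)
  start0 <- as.integer(start1 - 1)
  end0 <- as.integer(end1)
  tibble(
    gene = gene,
    chrom = vapply(fields, `[`, character(1), 1),
    start = start0, end = end0, strand = strand,
    tss = ifelse(strand == "-", end0 - 1L, start0)
  )
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  lines <- sprintf("%s\tchromabind\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   annotation$chrom, annotation$start + 1L, annotation$end,
                   annotation$strand, annotation$gene)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
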