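# Delimited-text I/O for Ct and RQ tables. SDS/RQ-Manager exports vary in
# shape (long vs wide) and in how non-detects are spelled; both dialects
# are explicit here and nothing is auto-detected.

.non_detect_spellings <- c("Undetermined", "undetermined", "NA", "")

.parse_ct_field <- function(x, decimal, where) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  num <- !(x %in% .non_detect_spellings) & !is.na(x)
  if (any(num)) {
    raw <- x[num]
    if (decimal == "comma") {
      if (any(grepl(".", raw, fixed = TRUE)))
        stop(sprintf("%s: found '.' in a decimal-comma file", where),
             call. = FALSE)
      raw <- gsub(",", ".", raw, fixed = TRUE)
    }
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(num)[which(is.na(val))[1]]
      stop(sprintf("%s: malformed Ct value '%s' (row %d)", where, x[bad], bad),
           call. = FALSE)
    }
    out[num] <- val
  }
  out
}

.read_delim <- function(path, sep) {
  utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, quote = "\"", comment.char = "",
                    na.strings = NULL)
}

#' Read a Ct table
#'
#' Reads threshold-cycle exports in either of two dialects. The long
#' dialect has one row per well with columns `sample`, `card`, `assay`,
#' optionally `assay_class`, and `ct`. The wide dialect has assays in rows
#' and samples in columns (first column = assay id) and requires a sidecar
#' card map, because card identity cannot be inferred from a wide table
#' and every downstream normalization is per card.
#'
#' `"Undetermined"`, `"undetermined"`, `"NA"` and empty fields all become
#' non-detects. Decimal commas (`"35,2"`) are only honoured when
#' `decimal = "comma"` is requested explicitly.
#'
#' @param path Path to the delimited file.
#' @param dialect `"long"` or `"wide"`.
#' @param cards For the wide dialect: a named character vector
#'   (sample -> card) or the path of a two-column (`sample`, `card`)
#'   delimited file.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @param decimal `"period"` (default) or `"comma"`.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, dialect = c("long", "wide"), cards = NULL,
                          sep = "\t", decimal = c("period", "comma")) {
  dialect <- match.arg(dialect)
  decimal <- match.arg(decimal)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- .read_delim(path, sep)

  if (dialect == "long") {
    needed <- c("sample", "card", "assay", "ct")
    missing_cols <- setdiff(needed, names(tab))
    if (length(missing_cols))
      stop("long Ct table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    key <- paste(tab$assay, tab$sample, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- tab[duplicated(key), c("assay", "sample")][1, ]
      stop(sprintf("duplicate (assay, sample) pair: (%s, %s)",
                   dup$assay, dup$sample), call. = FALSE)
    }
    ctv <- .parse_ct_field(tab$ct, decimal, path)
    assays <- unique(tab$assay)
    samples <- unique(tab$sample)
    values <- matrix(NA_real_, length(assays), length(samples),
                     dimnames = list(assays, samples))
    values[cbind(match(tab$assay, assays), match(tab$sample, samples))] <- ctv
    card <- tapply(tab$card, tab$sample, function(x) unique(x))
    if (any(lengths(card) != 1))
      stop("sample mapped to more than one card: ",
           paste(names(card)[lengths(card) != 1], collapse = ", "),
           call. = FALSE)
    card <- stats::setNames(unlist(card), names(card))
    assay_class <- NULL
    if ("assay_class" %in% names(tab)) {
      ac <- tapply(tab$assay_class, tab$assay, function(x) unique(x)[1])
      assay_class <- stats::setNames(as.character(ac), names(ac))
    }
    return(ct_matrix(values, card = card[samples], assay_class = assay_class))
  }

  # wide dialect
  if (is.null(cards))
    stop("wide dialect requires a `cards` sidecar (sample -> card)",
         call. = FALSE)
  if (is.character(cards) && length(cards) == 1 && file.exists(cards)) {
    cm <- .read_delim(cards, sep)
    if (!all(c("sample", "card") %in% names(cm)))
      stop("card map needs `sample` and `card` columns", call. = FALSE)
    cards <- stats::setNames(cm$card, cm$sample)
  }
  assays <- tab[[1]]
  if (anyDuplicated(assays))
    stop("duplicate assay id in wide table: ",
         assays[duplicated(assays)][1], call. = FALSE)
  samples <- names(tab)[-1]
  values <- matrix(NA_real_, length(assays), length(samples),
                   dimnames = list(assays, samples))
  for (j in seq_along(samples))
    values[, j] <- .parse_ct_field(tab[[j + 1]], decimal, path)
  unknown <- setdiff(samples, names(cards))
  if (length(unknown))
    stop("samples missing from the card map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ct_matrix(values, card = cards[samples])
}

.format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

.write_wide <- function(values, path, sep, first_col) {
  out <- data.frame(first = rownames(values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- first_col
  for (s in colnames(values)) out[[s]] <- .format_num(values[, s])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and re-read RQ tables
#'
#' Relative quantities are written as a wide delimited table (assay rows,
#' sample columns) at 15 significant digits; masked cells are written as
#' empty fields. `read_rq_table()` reads such a file back; a write/read
#' round trip reproduces values to 1e-12 and preserves the missing mask.
#'
#' @param rq An [rq_matrix()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `write_rq_table()` returns `path` invisibly; `read_rq_table()`
#'   an [rq_matrix()].
#' @export
write_rq_table <- function(rq, path, sep = "\t") {
  stopifnot(inherits(rq, "rq_matrix"))
  .write_wide(rq$rq, path, sep, "assay")
}

#' @rdname write_rq_table
#' @param reference_mode Reference convention to record on the re-read
#'   matrix (the table itself does not carry it).
#' @export
read_rq_table <- function(path, sep = "\t",
                          reference_mode = "virtual_housekeeping") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- .read_delim(path, sep)
  assays <- tab[[1]]
  samples <- names(tab)[-1]
  values <- matrix(NA_real_, length(assays), length(samples),
                   dimnames = list(assays, samples))
  for (j in seq_along(samples)) {
    x <- trimws(tab[[j + 1]])
    num <- !(x %in% c("", "NA"))
    values[num, j] <- as.numeric(x[num])
  }
  rq_matrix(values, reference_mode = reference_mode)
}

#' Write a Ct matrix
#'
#' Writes the wide dialect plus the card-map sidecar that
#' [read_ct_table()] requires; non-detects become empty fields.
#'
#' @param ct A [ct_matrix()].
#' @param path Output path for the wide Ct table.
#' @param cards_path Output path for the sample -> card sidecar.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, cards_path, sep = "\t") {
  stopifnot(inherits(ct, "ct_matrix"))
  .write_wide(ct$values, path, sep, "assay")
  utils::write.table(
    data.frame(sample = names(ct$card), card = unname(ct$card)),
    cards_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' One row per sample; controlled-vocabulary columns are validated by
#' [sample_annotation()].
#'
#' @param path Path to a delimited annotation file.
#' @param sep Field separator.
#' @param samples Optional sample ids the annotation must match exactly.
#' @return A [sample_annotation()] data frame.
#' @export
read_sample_annotation <- function(path, sep = "\t", samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  sample_annotation(tab, samples = samples)
}
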