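# Labeled hexapeptide datasets: construction, validation, file I/O.

#' Construct a labeled hexapeptide dataset
#'
#' A `peptide_dataset` is a data frame with columns `id`, `sequence` and
#' `label`. Sequences must be hexapeptides over the 20 standard one-letter
#' residue codes; labels are `"amyloid"`, `"non_amyloid"` (alias
#' `"non-amyloid"`) or `"unlabeled"`.
#'
#' Duplicate handling follows the convention used when redundant records are
#' eliminated from experimental compilations: a repeated (sequence, label)
#' pair is an error unless `allow_duplicates = TRUE`, and the same sequence
#' carrying two conflicting labels is an error regardless of that flag.
#' `check_duplicates = FALSE` disables both checks; it is used internally by
#' the synthetic generator, whose random draws can legitimately collide.
#'
#' @param sequence Character vector of hexapeptide sequences.
#' @param label Label per record (recycled); see above for accepted tokens.
#' @param id Optional identifiers; defaults to `pep_1 ... pep_n`.
#' @param allow_duplicates Permit repeated (sequence, label) pairs.
#' @param check_duplicates Set to `FALSE` to skip duplicate validation
#'   entirely (conflicting labels included).
#' @return A `peptide_dataset` (also a `data.frame`).
#' @seealso [read_peptides()], [class_sizes()]
#' @export
#' @examples
#' peptide_dataset(c("STVIIE", "VQIVYK"), c("amyloid", "non_amyloid"))
peptide_dataset <- function(sequence, label = "unlabeled", id = NULL,
                            allow_duplicates = FALSE,
                            check_duplicates = TRUE) {
  assert_sequences(sequence)
  label <- normalize_labels(rep_len(as.character(label), length(sequence)))
  id <- as.character(id %||% paste0("pep_", seq_along(sequence)))
  if (length(id) != length(sequence))
    stop("id must match the number of sequences", call. = FALSE)
  if (check_duplicates) {
    key <- paste(sequence, label, sep = "\r")
    if (!allow_duplicates && anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop(sprintf("duplicate record: sequence '%s' with label '%s'",
                   sub("\r.*", "", d), sub(".*\r", "", d)), call. = FALSE)
    }
    lab_per_seq <- tapply(as.character(label[label != "unlabeled"]),
                          sequence[label != "unlabeled"],
                          function(v) length(unique(v)))
    if (length(lab_per_seq) && any(lab_per_seq > 1)) {
      s <- names(lab_per_seq)[which(lab_per_seq > 1)[1]]
      stop(sprintf("sequence '%s' appears with conflicting labels", s),
           call. = FALSE)
    }
  }
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_dataset", "data.frame")
  out
}

#' Number of records per label
#'
#' @param ds A [peptide_dataset()].
#' @return Named integer vector over the labels `amyloid`, `non_amyloid`,
#'   `unlabeled`.
#' @export
class_sizes <- function(ds) {
  stopifnot(inherits(ds, "peptide_dataset"))
  tab <- table(factor(ds$label, levels = LABEL_LEVELS))
  stats::setNames(as.integer(tab), names(tab))
}

# records of one class, with validation
class_records <- function(ds, label) {
  stopifnot(inherits(ds, "peptide_dataset"))
  label <- as.character(normalize_labels(label)[1])
  sub <- ds[as.character(ds$label) == label, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("dataset contains no '%s' records", label), call. = FALSE)
  sub
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cs <- class_sizes(x)
  cat(sprintf("peptide_dataset: %d hexapeptides (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(cs), cs), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a labeled peptide dataset
#'
#' Reads hexapeptide records from a tab-separated file (`sequence<TAB>label`
#' per row, `#` comments allowed) or a FASTA file whose description lines are
#' `>id|label`. FASTA records without a `|label` suffix are `unlabeled`.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension: `.fa`, `.fasta`, `.faa` are FASTA),
#'   `"tsv"` or `"fasta"`.
#' @param allow_duplicates Permit repeated (sequence, label) pairs. A
#'   sequence with two conflicting labels is always an error.
#' @return A [peptide_dataset()], records in file order.
#' @export
read_peptides <- function(path, format = c("auto", "tsv", "fasta"),
                          allow_duplicates = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  if (format == "fasta") {
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0) stop("no FASTA records in file", call. = FALSE)
    hdr <- names(aas)
    has_label <- grepl("|", hdr, fixed = TRUE)
    label <- ifelse(has_label, sub("^.*\\|", "", hdr), "unlabeled")
    id <- sub("\\|[^|]*$", "", hdr)
    id[!has_label] <- hdr[!has_label]
    seqs <- as.character(aas)
  } else {
    lines <- readLines(path)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (length(keep) == 0) stop("no data rows in file", call. = FALSE)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 2))
      stop(sprintf("line %d: expected 'sequence<TAB>label', found %d field(s)",
                   keep[which(nf != 2)[1]], nf[which(nf != 2)[1]]),
           call. = FALSE)
    seqs <- trimws(vapply(fields, `[[`, "", 1L))
    label <- vapply(fields, `[[`, "", 2L)
    id <- paste0("pep_", seq_along(seqs))
  }
  peptide_dataset(seqs, label, id, allow_duplicates = allow_duplicates)
}

#' Write a peptide dataset
#'
#' @param ds A [peptide_dataset()].
#' @param path Output path.
#' @param format `"tsv"` writes `sequence<TAB>label` rows; `"fasta"` writes
#'   `>id|label` records.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(ds, path, format = c("tsv", "fasta")) {
  stopifnot(inherits(ds, "peptide_dataset"))
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(paste(ds$sequence, as.character(ds$label), sep = "\t"), path)
  } else {
    aas <- Biostrings::AAStringSet(ds$sequence)
    names(aas) <- paste(ds$id, as.character(ds$label), sep = "|")
    Biostrings::writeXStringSet(aas, path)
  }
  invisible(path)
}
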