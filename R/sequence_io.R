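# Reading, validating and writing peptide sequences and label tables.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes in alphabetical order. This
#' ordering is used everywhere a feature layout depends on residue order
#' (ASDC pair indices, BLOSUM62 row blocks, AAindex table columns).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
}

#' Validate and normalize a raw peptide sequence
#'
#' Uppercases the input and checks that every character is one of the 20
#' canonical residues and that the sequence has at least two residues
#' (pairwise descriptors and transition counts are undefined below that).
#'
#' @param raw Single character string, the candidate sequence.
#' @return The normalized (uppercased) sequence, invisibly classed as valid.
#'   Rejection raises a condition of class `"antioxpep_invalid_sequence"`
#'   naming the offending character and its position, or the length problem.
#' @export
#' @examples
#' validate_sequence("gshwy")   # "GSHWY"
#' try(validate_sequence("ACXD"))
validate_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop_invalid_sequence("sequence must be a single character string")
  }
  seq <- toupper(trimws(raw))
  if (nchar(seq) < 2L) {
    stop_invalid_sequence(sprintf(
      "sequence %s has length %d; minimum length is 2", dQuote(seq), nchar(seq)))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0L) {
    stop_invalid_sequence(sprintf(
      "noncanonical residue %s at position %d", dQuote(chars[bad[1]]), bad[1]))
  }
  seq
}

stop_invalid_sequence <- function(msg) {
  stop(structure(
    class = c("antioxpep_invalid_sequence", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

new_peptide_set <- function(id, seq, label = NULL) {
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.integer(label)
  class(df) <- c("peptide_set", "data.frame")
  df
}

#' Read peptides from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a
#' `peptide_set` data frame with columns `id` and `seq`. Residues are
#' uppercased; record order is preserved. Identifiers are the full header up
#' to the first whitespace. Headers carrying a `|1` / `|0` suffix are
#' interpreted as class labels (antioxidant / non-antioxidant) and stripped
#' from the id; a label table read with [read_labels()] takes precedence.
#'
#' @param path Path to a FASTA file.
#' @param drop_invalid If `TRUE`, records failing [validate_sequence()] are
#'   dropped with a warning instead of aborting the read.
#' @return A `peptide_set` data frame (columns `id`, `seq`, and `label` when
#'   labels were found in the headers) with one row per retained record.
#' @export
read_fasta <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(new_peptide_set(character(), character()))
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record ('>')",
                 nonempty[1]))
  }
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  labels <- rep(NA_integer_, length(ids))
  tagged <- grepl("\\|[01]$", ids)
  labels[tagged] <- as.integer(sub("^.*\\|", "", ids[tagged]))
  ids[tagged] <- sub("\\|[01]$", "", ids[tagged])
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw <- as.character(seqs)
  keep <- rep(TRUE, length(raw))
  norm <- character(length(raw))
  for (i in seq_along(raw)) {
    res <- tryCatch(validate_sequence(raw[i]),
                    antioxpep_invalid_sequence = function(e) e)
    if (inherits(res, "condition")) {
      if (drop_invalid) {
        warning(sprintf("dropping record '%s': %s", ids[i], conditionMessage(res)),
                call. = FALSE)
        keep[i] <- FALSE
      } else {
        stop(sprintf("record '%s': %s", ids[i], conditionMessage(res)),
             call. = FALSE)
      }
    } else {
      norm[i] <- res
    }
  }
  out <- new_peptide_set(ids[keep], norm[keep])
  if (any(!is.na(labels[keep]))) out$label <- labels[keep]
  out
}

#' Write peptides to a FASTA file
#'
#' @param peptides A `peptide_set` data frame (columns `id`, `seq`; an
#'   optional `label` column is appended to the header as `|<label>`).
#' @param path Output path.
#' @param with_labels Append `|label` to headers when a label column exists.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peptides, path, with_labels = FALSE) {
  ids <- peptides$id
  if (with_labels && !is.null(peptides$label)) {
    ids <- paste0(ids, "|", peptides$label)
  }
  writeLines(paste0(">", ids, "\n", peptides$seq), path)
  invisible(path)
}

#' Attach binary labels to a peptide set
#'
#' Reads a two-column tab-separated table with header `id<TAB>label` and
#' aligns labels to `peptides` by id. Every peptide must receive a label and
#' every table row must match a peptide; labels must be 0 (non-antioxidant)
#' or 1 (antioxidant). When the FASTA headers also carried labels the table
#' wins.
#'
#' @param path Path to the TSV label table.
#' @param peptides A `peptide_set` data frame.
#' @return `peptides` with an integer `label` column.
#' @export
read_labels <- function(path, peptides) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label table must have two columns: id, label")
  names(tab)[1:2] <- c("id", "label")
  missing_in_tab <- setdiff(peptides$id, tab$id)
  if (length(missing_in_tab) > 0L) {
    stop("no label for id(s): ", paste(missing_in_tab, collapse = ", "))
  }
  extra <- setdiff(tab$id, peptides$id)
  if (length(extra) > 0L) {
    stop("label table id(s) absent from sequences: ",
         paste(extra, collapse = ", "))
  }
  lab <- tab$label[match(peptides$id, tab$id)]
  if (!all(lab %in% c("0", "1"))) {
    bad <- unique(lab[!lab %in% c("0", "1")])
    stop("labels must be 0 or 1; found: ", paste(bad, collapse = ", "))
  }
  peptides$label <- as.integer(lab)
  peptides
}

#' @exportS3Method base::print
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set: %d sequence(s)%s\n", nrow(x),
              if (!is.null(x$label))
                sprintf(" (%d positive / %d negative)",
                        sum(x$label == 1L), sum(x$label == 0L)) else ""))
  NextMethod()
}
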