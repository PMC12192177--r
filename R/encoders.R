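# Descriptor encoders: map a validated peptide sequence to fixed-dimension
# numeric feature blocks, and concatenate blocks into fusion features.
#
# Canonical encoder order (fixes fusion layout): aaindex, asdc, blosum62, ctd.

ENCODER_NAMES <- c("aaindex", "asdc", "blosum62", "ctd")

new_feature_block <- function(values, labels, name) {
  stopifnot(length(values) == length(labels))
  names(values) <- labels
  structure(values, encoder = name, class = c("feature_block", "numeric"))
}

#' @exportS3Method base::print
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block '%s': %d dimensions\n", attr(x, "encoder"), length(x)))
  utils::str(unclass(x))
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Averaged physicochemical property encoding
#'
#' Encodes a peptide as the per-property average of its residues' AAindex
#' values: for property j, `F_j = (1/L) * sum_i v_j(residue_i)`. One
#' dimension per property in table order.
#'
#' @param seq A validated peptide sequence (see [validate_sequence()]).
#' @param table An `aaindex_table` from [load_aaindex()].
#' @return A `feature_block` with one dimension per property (544 for the
#'   bundled table), labeled `aaindex.<accession>`.
#' @export
encode_aaindex <- function(seq, table = load_aaindex()) {
  chars <- seq_chars(seq)
  counts <- tabulate(match(chars, aa_alphabet()), 20L)
  f <- as.vector(table$values %*% (counts / length(chars)))
  new_feature_block(f, paste0("aaindex.", table$properties), "aaindex")
}

ctd_milestone <- function(positions, L) {
  # Normalized sequence positions of the first, 25th/50th/75th-percentile
  # and last occurrence of a residue group; zeros when the group is absent.
  n <- length(positions)
  if (n == 0L) return(numeric(5))
  idx <- c(1L, pmax(1L, ceiling(c(0.25, 0.5, 0.75) * n)), n)
  positions[idx] / L
}

ctd_cumulative <- function(positions, L) {
  # Audit variant: share of the group's residues falling within the first
  # 0/25/50/75/100% of sequence positions.
  n <- length(positions)
  if (n == 0L) return(numeric(5))
  vapply(c(0, 0.25, 0.5, 0.75, 1), function(q) {
    sum(positions <= ceiling(q * L)) / n
  }, numeric(1))
}

#' Composition/transition/distribution (CTD) encoding
#'
#' For each of the 13 bundled physicochemical attributes, the 20 residues
#' are partitioned into 3 groups and the peptide is summarized by:
#' composition `C_g = N_g / L` (3 values); transition
#' `T_gh = (N_gh + N_hg) / (L - 1)` for the unordered group pairs
#' \{1,2\}, \{1,3\}, \{2,3\}, where `N_gh` counts adjacent residue pairs
#' moving from group g to group h (3 values); and distribution: the
#' normalized sequence positions at which the first, 25%, 50%, 75% and
#' 100% milestones of each group occur (15 values). Layout: 13 properties
#' x (3 C + 3 T + 15 D) = 273 dimensions.
#'
#' A group absent from the sequence contributes 0 to its composition and
#' all five of its distribution slots.
#'
#' @param seq A validated peptide sequence.
#' @param grouping A `ctd_grouping` from [load_ctd_groups()].
#' @param d_variant Distribution formulation: `"milestone"` (default, the
#'   conventional CTD distribution descriptor) or `"cumulative"` (cumulative group
#'   share within the first k% of positions, retained for auditability).
#' @return A 273-dimensional `feature_block`.
#' @export
encode_ctd <- function(seq, grouping = load_ctd_groups(),
                       d_variant = c("milestone", "cumulative")) {
  d_variant <- match.arg(d_variant)
  dfun <- if (d_variant == "milestone") ctd_milestone else ctd_cumulative
  chars <- seq_chars(seq)
  L <- length(chars)
  res_idx <- match(chars, aa_alphabet())
  vals <- numeric(0)
  labels <- character(0)
  pair_names <- c("T12", "T13", "T23")
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (prop in grouping$properties) {
    g <- grouping$groups[[prop]][res_idx]
    comp <- tabulate(g, 3L) / L
    a <- g[-L]; b <- g[-1L]
    trans <- vapply(pairs, function(p) {
      sum((a == p[1] & b == p[2]) | (a == p[2] & b == p[1])) / (L - 1)
    }, numeric(1))
    dist <- unlist(lapply(1:3, function(k) dfun(which(g == k), L)))
    vals <- c(vals, comp, trans, dist)
    labels <- c(labels,
                paste0("ctd.", prop, ".",
                       c(paste0("C", 1:3), pair_names,
                         paste0("D", rep(1:3, each = 5), ".p",
                                rep(c(0, 25, 50, 75, 100), 3)))))
  }
  new_feature_block(vals, labels, "ctd")
}

#' Adaptive skip dipeptide composition (ASDC) encoding
#'
#' Counts every ordered residue pair `(residue_i, residue_j)` with `i < j`
#' (all sequence separations, not just adjacency) and normalizes by the
#' total pair count `L(L-1)/2`, so the 400-dimensional vector is a
#' probability distribution over ordered amino-acid pairs. Pairs are laid
#' out row-major in alphabetical residue order (AA, AC, ..., YY).
#'
#' @param seq A validated peptide sequence (length >= 2).
#' @return A 400-dimensional `feature_block` summing to 1.
#' @export
encode_asdc <- function(seq) {
  alpha <- aa_alphabet()
  idx <- match(seq_chars(seq), alpha)
  L <- length(idx)
  counts <- matrix(0, 20, 20)
  for (i in seq_len(L - 1L)) {
    later <- tabulate(idx[(i + 1L):L], 20L)
    counts[idx[i], ] <- counts[idx[i], ] + later
  }
  total <- L * (L - 1L) / 2
  labels <- paste0("asdc.", as.vector(t(outer(alpha, alpha, paste0))))
  new_feature_block(as.vector(t(counts)) / total, labels, "asdc")
}

#' Frequency-weighted BLOSUM62 substitution profile encoding
#'
#' For each residue `a` in alphabetical order, the block `freq(a) * row_a`
#' is emitted, where `freq(a)` is the relative frequency of `a` in the
#' peptide and `row_a` is that residue's 21-entry row of the zero-column
#' extended BLOSUM62 matrix. Residues absent from the peptide contribute
#' all-zero blocks, so the encoding has a fixed width of 20 x 21 = 420
#' regardless of peptide length.
#'
#' @param seq A validated peptide sequence.
#' @param matrix A `substitution_matrix` from [load_blosum62()].
#' @return A 420-dimensional `feature_block` labeled
#'   `blosum62.<residue>.<column>`.
#' @export
encode_blosum62 <- function(seq, matrix = load_blosum62()) {
  chars <- seq_chars(seq)
  freq <- tabulate(match(chars, aa_alphabet()), 20L) / length(chars)
  block <- matrix * freq           # recycles freq down the 20 rows
  labels <- paste0("blosum62.", rep(rownames(matrix), each = ncol(matrix)),
                   ".", rep(colnames(matrix), times = nrow(matrix)))
  new_feature_block(as.vector(t(block)), labels, "blosum62")
}

#' Enumerate descriptor combinations
#'
#' All non-empty subsets of the base encoders, each in canonical member
#' order (aaindex, asdc, blosum62, ctd), listed singletons first and then
#' by increasing subset size. With the four standard encoders this yields
#' 15 combinations, 11 of which are true fusions (size >= 2).
#'
#' @param base Character vector of encoder names (duplicate-free subset of
#'   `c("aaindex", "asdc", "blosum62", "ctd")`).
#' @return A list of character vectors, each a feature-set specification.
#' @export
#' @examples
#' length(enumerate_feature_sets())                     # 15
#' sum(lengths(enumerate_feature_sets()) >= 2)          # 11
enumerate_feature_sets <- function(base = ENCODER_NAMES) {
  if (length(base) == 0L) stop("base encoder list must be non-empty")
  if (anyDuplicated(base)) stop("base encoder list has duplicates")
  base <- canonical_spec(base)
  sets <- list()
  for (size in seq_along(base)) {
    combos <- utils::combn(base, size, simplify = FALSE)
    sets <- c(sets, combos)
  }
  sets
}

canonical_spec <- function(members) {
  members <- unique(members)
  bad <- setdiff(members, ENCODER_NAMES)
  if (length(bad) > 0L) {
    stop("unknown encoder(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(ENCODER_NAMES, collapse = ", "))
  }
  ENCODER_NAMES[ENCODER_NAMES %in% members]
}

#' Fused (concatenated) descriptor encoding
#'
#' Concatenates the requested encoder blocks in canonical order, regardless
#' of the order given, so feature indices are stable across runs.
#'
#' @param seq A validated peptide sequence.
#' @param members Character vector of encoder names to fuse (any non-empty
#'   subset of the four encoders).
#' @param resources Resource bundle from [load_resources()].
#' @param ... Passed on to individual encoders (e.g. `d_variant`).
#' @return A `feature_block` whose dimension is the sum of the member
#'   dimensions (e.g. ctd + blosum62 = 273 + 420 = 693).
#' @export
encode_fusion <- function(seq, members, resources = load_resources(), ...) {
  members <- canonical_spec(members)
  blocks <- lapply(members, function(m) {
    switch(m,
           aaindex  = encode_aaindex(seq, resources$aaindex),
           asdc     = encode_asdc(seq),
           blosum62 = encode_blosum62(seq, resources$blosum62),
           ctd      = encode_ctd(seq, resources$ctd, ...))
  })
  vals <- unlist(lapply(blocks, unclass), use.names = TRUE)
  new_feature_block(as.numeric(vals), names(vals), paste(members, collapse = "+"))
}

#' Encode a whole peptide set into a feature matrix
#'
#' Row-binds [encode_fusion()] over all sequences of a peptide set.
#'
#' @param peptides A `peptide_set` data frame.
#' @param members Encoder names to fuse.
#' @param resources Resource bundle from [load_resources()].
#' @param ... Passed to the encoders.
#' @return Numeric matrix, one row per peptide (rownames = ids), one column
#'   per feature dimension (colnames = feature labels).
#' @export
encode_peptides <- function(peptides, members, resources = load_resources(), ...) {
  members <- canonical_spec(members)
  rows <- lapply(peptides$seq, encode_fusion, members = members,
                 resources = resources, ...)
  mat <- do.call(rbind, lapply(rows, unclass))
  rownames(mat) <- peptides$id
  mat
}

#' Write a feature matrix as a TSV table
#'
#' First column `id`, then one labeled column per feature dimension. The
#' numeric formatting is fixed (15 significant digits) so identical inputs
#' produce byte-identical files.
#'
#' @param mat Feature matrix from [encode_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(mat, path) {
  df <- data.frame(id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
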