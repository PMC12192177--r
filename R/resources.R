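# Loaders for the three bundled lookup tables the encoders depend on:
# the AAindex physicochemical property table, the (zero-column extended)
# BLOSUM62 substitution matrix, and the 13-property CTD grouping table.

res_path <- function(file) {
  p <- system.file("extdata", file, package = "antioxpep")
  if (p == "") stop("bundled resource not found: ", file)
  p
}

#' Load the amino-acid property table
#'
#' Loads the bundled AAindex physicochemical property table: one row per
#' index (property), one numeric value per canonical residue. The bundled
#' copy is the table distributed with the seqinr project (AAindex release
#' 9.1, 544 indices); later database releases carry 566. Missing raw entries
#' (a few indices lack values for some residues) are imputed with the mean
#' of that property's available residue values, and imputed cells are
#' flagged in the `imputed` matrix so downstream users can exclude them.
#'
#' @param rescale If `TRUE`, each property is min-max scaled to \[0, 1\]
#'   across the 20 residues after imputation. Off by default: the encoder
#'   averages raw property values.
#' @return An object of class `aaindex_table`: a list with `properties`
#'   (ordered accession ids), `values` (properties x 20 numeric matrix,
#'   columns in [aa_alphabet()] order), `imputed` (logical matrix of the
#'   same shape), and `n_properties`.
#' @export
load_aaindex <- function(rescale = FALSE) {
  parts <- lapply(c("aaindex_part1.tsv", "aaindex_part2.tsv"), function(f) {
    utils::read.delim(res_path(f), comment.char = "#", header = TRUE,
                      check.names = FALSE)
  })
  tab <- rbind(parts[[1]], parts[[2]])
  alpha <- aa_alphabet()
  if (!identical(colnames(tab), c("accession", alpha))) {
    stop("AAindex resource is corrupt: unexpected column layout")
  }
  if (anyDuplicated(tab$accession)) {
    stop("AAindex resource is corrupt: duplicate accession")
  }
  vals <- as.matrix(tab[, alpha])
  rownames(vals) <- tab$accession
  imputed <- is.na(vals)
  if (any(imputed)) {
    means <- rowMeans(vals, na.rm = TRUE)
    idx <- which(imputed, arr.ind = TRUE)
    vals[imputed] <- means[idx[, 1]]
  }
  if (any(!is.finite(vals))) stop("AAindex resource is corrupt: non-finite values")
  if (rescale) {
    rng <- apply(vals, 1, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    vals <- (vals - rng[1, ]) / span
  }
  structure(list(properties = tab$accession, values = vals, imputed = imputed,
                 n_properties = nrow(vals),
                 na_policy = "per-property mean over available residues",
                 rescaled = rescale),
            class = "aaindex_table")
}

#' Load the extended BLOSUM62 substitution matrix
#'
#' Reads the bundled BLOSUM62 matrix (standard NCBI text layout), reorders
#' rows and columns to the alphabetical residue order used throughout the
#' package, verifies symmetry of the 20 x 20 block, and appends a 21st
#' all-zero column (`pad`). The zero column pads each residue's substitution
#' profile so the per-residue feature blocks have a fixed width of 21.
#'
#' @return A 20 x 21 integer matrix of class `substitution_matrix`; rows are
#'   named by residue in [aa_alphabet()] order, columns by residue plus
#'   `"pad"`.
#' @export
load_blosum62 <- function() {
  lines <- readLines(res_path("blosum62.txt"))
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 20L) stop("BLOSUM62 resource is corrupt: expected 20 columns")
  body <- do.call(rbind, lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]]))
  if (nrow(body) != 20L) stop("BLOSUM62 resource is corrupt: expected 20 rows")
  m <- matrix(as.integer(body[, -1]), nrow = 20,
              dimnames = list(body[, 1], header))
  alpha <- aa_alphabet()
  if (!setequal(rownames(m), alpha)) stop("BLOSUM62 resource is corrupt: bad residues")
  m <- m[alpha, alpha]
  if (!isSymmetric(unname(m))) stop("BLOSUM62 resource is corrupt: asymmetric block")
  ext <- cbind(m, pad = 0L)
  class(ext) <- c("substitution_matrix", class(ext))
  ext
}

#' Load the CTD property grouping table
#'
#' Loads the bundled three-group residue partitions for the 13
#' physicochemical attributes used by the composition/transition/
#' distribution descriptors (seven hydrophobicity scales, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary structure, and
#' solvent accessibility). Each attribute must partition all 20 residues
#' into exactly three non-empty groups.
#'
#' @return An object of class `ctd_grouping`: a list with `properties`
#'   (ordered attribute names) and `groups`, a named list mapping each
#'   attribute to an integer vector over [aa_alphabet()] with values in
#'   1..3 (the group index of each residue).
#' @export
load_ctd_groups <- function() {
  tab <- utils::read.delim(res_path("ctd_groups.tsv"), comment.char = "#",
                           header = TRUE, colClasses = "character")
  alpha <- aa_alphabet()
  groups <- lapply(seq_len(nrow(tab)), function(i) {
    g <- integer(20)
    names(g) <- alpha
    for (k in 1:3) {
      res <- strsplit(tab[[paste0("group", k)]][i], "", fixed = TRUE)[[1]]
      if (length(res) == 0L) {
        stop("CTD resource is corrupt: empty group ", k, " for ", tab$property[i])
      }
      g[res] <- k
    }
    if (any(g == 0L)) {
      stop("CTD resource is corrupt: unassigned residue(s) for ", tab$property[i])
    }
    counts <- tabulate(g, 3)
    if (sum(counts) != 20L || any(counts == 0L)) {
      stop("CTD resource is corrupt: bad partition for ", tab$property[i])
    }
    g
  })
  names(groups) <- tab$property
  if (length(groups) != 13L) {
    stop("CTD resource is corrupt: expected 13 properties, found ", length(groups))
  }
  structure(list(properties = tab$property, groups = groups),
            class = "ctd_grouping")
}

#' Load all encoder resources at once
#'
#' Convenience wrapper used by [encode_fusion()], [encode_peptides()] and
#' the command-line interface.
#'
#' @inheritParams load_aaindex
#' @return A list with elements `aaindex`, `blosum62`, `ctd`.
#' @export
load_resources <- function(rescale = FALSE) {
  list(aaindex = load_aaindex(rescale = rescale),
       blosum62 = load_blosum62(),
       ctd = load_ctd_groups())
}

#' Versions and checksums of the bundled resource files
#'
#' @return Named character vector of md5 checksums, one per resource file.
#' @export
resource_hashes <- function() {
  files <- c("aaindex_part1.tsv", "aaindex_part2.tsv", "blosum62.txt",
             "ctd_groups.tsv")
  vapply(files, function(f) unname(tools::md5sum(res_path(f))), character(1))
}
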