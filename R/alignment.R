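#' Haplotype alignment of a non-recombining haploid locus
#'
#' Container for per-sample state vectors over the surveyed polymorphic
#' sites of a single haploid, non-recombining locus (e.g. the MSY), plus the
#' population assignment of every sample and the total surveyed length in bp.
#' Only polymorphic columns need be stored; `locus_length_bp` carries the
#' monomorphic remainder, which matters only for per-bp rates.
#'
#' @param seqs character matrix, samples x sites; states in `A,C,G,T,N` or
#'   `0,1` (derived/ancestral coding). Row names are sample ids.
#' @param populations named character vector mapping sample id to population
#'   code, or an unnamed vector in row order.
#' @param locus_length_bp integer, total surveyed length; must be at least
#'   the number of stored site columns.
#' @param ancestral optional character vector of per-site ancestral states.
#' @return An object of class `haplotype_alignment`: a list with elements
#'   `seqs`, `populations`, `locus_length_bp`, `ancestral`.
#' @export
haplotype_alignment <- function(seqs, populations, locus_length_bp,
                                ancestral = NULL) {
  if (!is.matrix(seqs)) seqs <- matrix(seqs, nrow = length(seqs))
  storage.mode(seqs) <- "character"
  seqs[] <- toupper(seqs)
  ids <- rownames(seqs)
  if (is.null(ids)) stop("sequence matrix must have sample ids as row names")
  if (anyDuplicated(ids)) stop("duplicate sample id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(names(populations))) {
    if (length(populations) != nrow(seqs))
      stop("populations must be named by sample id or match the row count")
    names(populations) <- ids
  }
  if (!all(ids %in% names(populations)))
    stop("every sample must map to a known population")
  populations <- as.character(populations[ids])
  names(populations) <- ids
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "N", "0", "1"))
  if (length(bad)) stop("invalid states in alignment: ", paste(bad, collapse = ","))
  locus_length_bp <- as.integer(locus_length_bp)
  if (is.na(locus_length_bp) || locus_length_bp < ncol(seqs))
    stop("locus_length_bp (", locus_length_bp,
         ") smaller than number of site columns (", ncol(seqs), ")")
  if (!is.null(ancestral) && length(ancestral) != ncol(seqs))
    stop("ancestral states must be one per site column")
  structure(list(seqs = seqs, populations = populations,
                 locus_length_bp = locus_length_bp, ancestral = ancestral),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", nrow(x$seqs), "samples,", ncol(x$seqs),
      "polymorphic sites,", length(unique(x$populations)), "populations,",
      "locus", x$locus_length_bp, "bp\n")
  invisible(x)
}

#' Number of samples and sites in an alignment
#' @param x a `haplotype_alignment`
#' @export
n_samples <- function(x) nrow(x$seqs)

#' Restrict an alignment to a subset of samples or populations
#'
#' @param x a `haplotype_alignment`
#' @param samples sample ids to keep, or NULL
#' @param populations population codes to keep, or NULL
#' @return a `haplotype_alignment` with the selected samples
#' @export
subset_alignment <- function(x, samples = NULL, populations = NULL) {
  keep <- rownames(x$seqs)
  if (!is.null(populations)) keep <- keep[x$populations[keep] %in% populations]
  if (!is.null(samples)) keep <- intersect(keep, samples)
  if (!length(keep)) stop("no samples left after subsetting")
  haplotype_alignment(x$seqs[keep, , drop = FALSE], x$populations[keep],
                      x$locus_length_bp,
                      ancestral = x$ancestral)
}

#' Read a haplotype alignment from FASTA or a polymorphic-site table
#'
#' FASTA headers must be `sampleID|populationCode`. A site table is a TSV
#' whose first two columns are `sample_id` and `population`, followed by one
#' column per polymorphic site; empty or NA cells become the missing state N.
#'
#' @param path file path.
#' @param format `"fasta"` or `"site_table"`.
#' @param locus_length_bp total surveyed locus length in bp.
#' @return a [haplotype_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "site_table"),
                           locus_length_bp) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    dna <- ape::read.FASTA(path)
    charlist <- as.character(dna)
    lens <- lengths(charlist)
    if (length(unique(lens)) > 1L)
      stop("ragged sequence lengths in FASTA: ",
           paste(unique(lens), collapse = ","))
    chars <- toupper(do.call(rbind, charlist))
    hdr <- strsplit(names(dna), "|", fixed = TRUE)
    if (any(lengths(hdr) != 2L))
      stop("FASTA headers must be 'sampleID|populationCode'")
    ids <- vapply(hdr, `[`, "", 1L)
    pops <- vapply(hdr, `[`, "", 2L)
    chars[!chars %in% c("A", "C", "G", "T", "0", "1")] <- "N"
    rownames(chars) <- ids
    haplotype_alignment(chars, stats::setNames(pops, ids), locus_length_bp)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE)
    if (!all(c("sample_id", "population") == names(tab)[1:2]))
      stop("site table must start with columns sample_id, population")
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
    m[is.na(m) | m == ""] <- "N"
    rownames(m) <- tab$sample_id
    haplotype_alignment(m, stats::setNames(tab$population, tab$sample_id),
                        locus_length_bp)
  }
}

#' Read per-population metadata
#'
#' TSV with header `code, ethnicity, language_family, region, latitude,
#' longitude, residence`. Residence values outside
#' patrilocal/matrilocal/neutral are mapped to `unknown` with a warning.
#'
#' @param path TSV file path.
#' @return data.frame, one row per population, with validated coordinates.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("code", "ethnicity", "language_family", "region",
            "latitude", "longitude", "residence")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$code))
    stop("duplicate population code: ",
         paste(unique(md$code[duplicated(md$code)]), collapse = ", "))
  if (any(abs(md$latitude) > 90) || any(abs(md$longitude) > 180))
    stop("coordinates out of range (|lat|<=90, |lon|<=180)")
  ok <- c("patrilocal", "matrilocal", "neutral", "unknown")
  bad <- !(md$residence %in% ok)
  if (any(bad)) {
    warning("unknown residence value(s) mapped to 'unknown': ",
            paste(unique(md$residence[bad]), collapse = ", "))
    md$residence[bad] <- "unknown"
  }
  md
}

#' Collapse an alignment into distinct haplotypes with per-population counts
#'
#' Identical state vectors are merged. Under `complete_deletion` every site
#' column containing any missing state (N) is removed first, so haplotype
#' identity is defined on a common site set; under `strict` any missing
#' state is an error.
#'
#' @param alignment a [haplotype_alignment()].
#' @param missing_policy `"complete_deletion"` or `"strict"`.
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (haplotype x site state matrix), `counts` (population x haplotype
#'   integer matrix) and `assignment` (per-sample haplotype id).
#' @export
collapse_haplotypes <- function(alignment,
                                missing_policy = c("complete_deletion", "strict")) {
  missing_policy <- match.arg(missing_policy)
  m <- alignment$seqs
  has_n <- m == "N"
  if (missing_policy == "strict" && any(has_n))
    stop("missing states present under strict policy")
  keep <- !apply(has_n, 2, any)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L && ncol(alignment$seqs) > 0L)
    stop_degenerate("no sites remain after complete deletion of missing columns")
  key <- apply(m, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  hap_ids <- paste0("H", seq_len(sum(uniq)))
  names(hap_ids) <- key[uniq]
  assignment <- hap_ids[key]
  names(assignment) <- rownames(m)
  counts <- table(alignment$populations, factor(assignment, levels = hap_ids))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(haplotypes = m[uniq, , drop = FALSE] |>
                   `rownames<-`(hap_ids),
                 counts = counts, assignment = assignment),
            class = "haplotype_table")
}

#' Matrix of pairwise sequence differences
#'
#' Entry (i,j) is the number of sites at which samples i and j carry
#' differing non-missing states, under pairwise deletion (sites compared
#' wherever both states are observed) or after complete deletion of columns
#' with any missing state.
#'
#' @param alignment a [haplotype_alignment()].
#' @param missing_policy `"pairwise_deletion"` or `"complete_deletion"`.
#' @return a [distance_matrix()] of kind `pairwise_diff`.
#' @export
pairwise_difference_matrix <- function(alignment,
                                       missing_policy = c("pairwise_deletion",
                                                          "complete_deletion")) {
  missing_policy <- match.arg(missing_policy)
  m <- alignment$seqs
  if (nrow(m) < 2L) stop_degenerate("need at least 2 samples")
  if (missing_policy == "complete_deletion")
    m <- m[, !apply(m == "N", 2, any), drop = FALSE]
  states <- setdiff(unique(as.vector(m)), "N")
  obs <- (m != "N") * 1L
  matches <- matrix(0, nrow(m), nrow(m))
  for (s in states) {
    x <- (m == s) * 1L
    matches <- matches + tcrossprod(x)
  }
  comparable <- tcrossprod(obs)
  d <- comparable - matches
  diag(d) <- 0
  distance_matrix(d, labels = rownames(m), kind = "pairwise_diff")
}

#' Labelled square distance/similarity matrix
#'
#' @param values square numeric matrix, symmetric with zero diagonal.
#' @param labels row/column labels.
#' @param kind one of `phist`, `dA`, `geographic`, `pairwise_diff`.
#' @export
distance_matrix <- function(values, labels = rownames(values),
                            kind = c("pairwise_diff", "phist", "dA",
                                     "geographic")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (max(abs(values - t(values)), 0) > 1e-12) stop("matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(labels)) labels <- paste0("X", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, kind = kind),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$kind, "), ", length(x$labels), " labels\n", sep = "")
  print(utils::head(x$values, 6L))
  invisible(x)
}

#' Write a labelled matrix / read it back
#'
#' TSV round-trip preserves values to at least 12 significant digits;
#' labels containing whitespace are quoted.
#'
#' @param matrix a [distance_matrix()] or plain numeric matrix.
#' @param path output path.
#' @export
write_matrix <- function(matrix, path) {
  v <- if (inherits(matrix, "distance_matrix")) matrix$values else matrix
  if (length(v) == 0L) warning("writing empty matrix: header-only file")
  df <- data.frame(label = rownames(v),
                   format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df[[1]]
  colnames(v) <- rownames(v)
  v
}

#' Write/read a data frame as TSV
#' @param rows data.frame.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  if (nrow(rows) == 0L) warning("writing empty table: header-only file")
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(rows, path, sep = "\t", quote = TRUE, row.names = FALSE)
  invisible(path)
}
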