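# ITS variants: per-collection consensus sequences over a fixed alignment
# are collapsed into equivalence classes ("variants") by exact
# column-by-column identity. Gaps are significant characters (indels are
# treated as insertions, i.e. alignment columns count), and IUPAC ambiguity
# codes are by default compared as literal symbols, because consensus
# sequences of unphased dikaryon material legitimately retain ambiguities.
# Pairwise distances between variants are Hamming distances over alignment
# columns.

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.check_alignment <- function(seqs) {
  if (!length(seqs)) stop("no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("unequal sequence lengths: sequences must come from one alignment")
  bad <- grepl(paste0("[^", paste(names(.iupac_sets), collapse = ""), "U.-]"),
               seqs)
  if (any(bad))
    stop("non-IUPAC character in sequence ", sQuote(names(seqs)[bad][1]))
  chartr(".", "-", seqs)
}

#' Collapse aligned consensus sequences into ITS variants
#'
#' Two sequences belong to the same variant iff they are identical position
#' by position across the alignment; gap characters are compared like any
#' other symbol. With `relaxed = TRUE`, two symbols also match when their
#' IUPAC base sets intersect (an optional mode, off by default).
#'
#' @param seqs Named character vector of aligned sequences (equal lengths),
#'   or the result of [read_aligned_fasta()].
#' @param labels Optional data frame with columns `id`, `species`, `region`
#'   labelling the sequences (see [read_variant_labels()]).
#' @param relaxed Logical; compare compatible ambiguity codes as equal
#'   (default `FALSE`, literal comparison).
#' @return An object of class `variant_classes`: list with `classes` (a
#'   data frame: `variant`, `representative`, `n_members`), `members`
#'   (list of id vectors per variant), `sequences` (representative
#'   residues) and `labels`.
#' @examples
#' v <- collapse_variants(c(a = "ACGT", b = "ACGT", c = "ACTT"))
#' v$classes$n_members  # 2, 1
#' @export
collapse_variants <- function(seqs, labels = NULL, relaxed = FALSE) {
  seqs <- .check_alignment(seqs)
  if (!relaxed) {
    grp <- match(seqs, unique(seqs))
  } else {
    # transitive closure is not wanted: relaxed matching is pairwise, so we
    # greedily assign each sequence to the first earlier class it matches
    grp <- integer(length(seqs)); reps <- character()
    for (i in seq_along(seqs)) {
      hit <- 0L
      for (j in seq_along(reps)) {
        if (.relaxed_equal(seqs[[i]], reps[[j]])) { hit <- j; break }
      }
      if (hit == 0L) { reps <- c(reps, seqs[[i]]); hit <- length(reps) }
      grp[i] <- hit
    }
  }
  ids <- names(seqs)
  members <- split(ids, grp)
  rep_seq <- vapply(members, function(m) seqs[[m[1]]], character(1))
  ord <- order(-lengths(members), vapply(members, `[[`, character(1), 1))
  members <- members[ord]; rep_seq <- rep_seq[ord]
  vn <- sprintf("V%02d", seq_along(members))
  names(members) <- vn; names(rep_seq) <- vn
  out <- list(
    classes = data.frame(variant = vn,
                         representative = vapply(members, `[[`, character(1), 1),
                         n_members = lengths(members),
                         stringsAsFactors = FALSE, row.names = NULL),
    members = members, sequences = rep_seq, labels = labels,
    relaxed = relaxed
  )
  class(out) <- "variant_classes"
  out
}

.relaxed_equal <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  for (k in seq_along(ca)) {
    x <- ca[k]; y <- cb[k]
    if (x == y) next
    if (x == "-" || y == "-") return(FALSE)
    if (!length(intersect(.iupac_sets[[x]], .iupac_sets[[y]])))
      return(FALSE)
  }
  TRUE
}

#' @export
print.variant_classes <- function(x, ...) {
  cat(sprintf("ITS variants: %d classes from %d sequences%s\n",
              nrow(x$classes), sum(x$classes$n_members),
              if (x$relaxed) " (relaxed ambiguity matching)" else ""))
  print(utils::head(x$classes, 10), row.names = FALSE)
  if (nrow(x$classes) > 10) cat("  ...\n")
  invisible(x)
}

#' Pairwise Hamming distances between ITS variants
#'
#' Column-by-column difference counts between variant representatives; a
#' gap opposite a base counts as one difference. Two variants joined by an
#' unsegmented network edge differ in exactly 1 position.
#'
#' @param variants A `variant_classes` object.
#' @return A symmetric integer matrix with variant names on both margins.
#' @export
pairwise_differences <- function(variants) {
  seqs <- variants$sequences
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(m)
  split_seqs <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sum(split_seqs[[i]] != split_seqs[[j]])
    m[i, j] <- d; m[j, i] <- d
  }
  m
}

#' Variants shared between species or regions
#'
#' For every variant, lists the species and region labels represented among
#' its members, and summarises how many collections sit in variants shared
#' by two or more species (or regions).
#'
#' @param variants A `variant_classes` with `labels` attached.
#' @return An object of class `shared_variant_table`: list with
#'   `by_variant` (data frame: variant, n_members, species, regions,
#'   shared_species, shared_region), `species_sharing` (data frame: per
#'   species, collections in variants shared with another species) and
#'   `region_sharing`.
#' @export
shared_variant_table <- function(variants) {
  lab <- variants$labels
  if (is.null(lab)) stop("variants carry no labels; pass labels= to collapse_variants()")
  need <- c("id", "species", "region")
  if (!all(need %in% names(lab)))
    stop("labels must have columns id, species, region")
  rows <- lapply(names(variants$members), function(vn) {
    ids <- variants$members[[vn]]
    li <- lab[match(ids, lab$id), , drop = FALSE]
    sp <- sort(unique(li$species)); rg <- sort(unique(li$region))
    data.frame(variant = vn, n_members = length(ids),
               species = paste(sp, collapse = "|"),
               regions = paste(rg, collapse = "|"),
               shared_species = length(sp) > 1L,
               shared_region = length(rg) > 1L,
               stringsAsFactors = FALSE)
  })
  by_variant <- do.call(rbind, rows)
  share_of <- function(what) {
    shared_vn <- by_variant$variant[by_variant[[paste0("shared_", what)]]]
    lv <- unlist(lapply(shared_vn, function(vn) {
      ids <- variants$members[[vn]]
      lab[[if (what == "species") "species" else "region"]][match(ids, lab$id)]
    }))
    if (!length(lv))
      return(data.frame(label = character(), n_in_shared = integer(),
                        stringsAsFactors = FALSE))
    tab <- table(lv)
    data.frame(label = names(tab), n_in_shared = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- list(by_variant = by_variant,
              species_sharing = share_of("species"),
              region_sharing = share_of("region"))
  class(out) <- "shared_variant_table"
  out
}

#' @export
print.shared_variant_table <- function(x, ...) {
  cat(sprintf("Shared-variant table: %d variants, %d shared between species\n",
              nrow(x$by_variant), sum(x$by_variant$shared_species)))
  if (nrow(x$species_sharing)) {
    cat("  collections in species-shared variants:\n")
    for (i in seq_len(nrow(x$species_sharing)))
      cat(sprintf("    %-18s %d\n", x$species_sharing$label[i],
                  x$species_sharing$n_in_shared[i]))
  }
  invisible(x)
}

# ---- I/O --------------------------------------------------------------------

#' Read an aligned FASTA file
#'
#' Uses Biostrings when available. All sequences must have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of sequences.
#' @export
read_aligned_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  x <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  .check_alignment(seqs)
}

#' Write aligned sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Read a variant label table
#'
#' A CSV with columns `id`, `species`, `region`.
#'
#' @param path Path to the label CSV.
#' @return A data frame.
#' @export
read_variant_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "region")
  if (!all(need %in% names(d)))
    stop("label file must have columns id, species, region")
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dist_matrix Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_square <- function(dist_matrix, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(dist_matrix)
  writeLines(sprintf("%5d", n), con)
  nm <- substr(sprintf("%-10s", rownames(dist_matrix)), 1, 10)
  for (i in seq_len(n))
    writeLines(paste0(nm[i], paste(sprintf("%g", dist_matrix[i, ]),
                                   collapse = "  ")), con)
  invisible(path)
}
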