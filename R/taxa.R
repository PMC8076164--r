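# Machine-readable trait database for the 28 Hebeloma species recognised
# from Greenland, compiled from the species descriptions: "on ave." spore
# ranges are per-collection-mean ranges (the keys compare collection means),
# O/P/D codes keep the parenthetical rare-state notation, and qualitative
# characters are the booleans/categories the keys actually consult.

.sections <- c("Hebeloma", "Denudata", "Velutipes", "Naviculospora")
.subsections <- c("Crustuliniformia", "Clepsydroida", "Hiemalia")
.cheilo_forms <- c("hourglass", "apex_swollen_stipitate", "gently_clavate",
                   "ventricose_lageniform", "mixed")
.spore_shapes <- c("ellipsoid", "amygdaloid", "limoniform", "fusoid", "mixed")
.papilla_levels <- c("absent", "indistinct", "distinct", "very_strong")

#' Load the species trait database
#'
#' Reads the packaged JSON trait database (or a user file with the same
#' schema) into a list of `taxon_record` objects, validating sections,
#' interval orientation, O/P/D codes and uniqueness of species names.
#'
#' @param path Path to a trait-database JSON file; defaults to the packaged
#'   database of the 28 Greenland species.
#' @return An object of class `taxon_db`: a named list of `taxon_record`s.
#' @examples
#' taxa <- load_taxa()
#' length(taxa)            # 28
#' taxa$grandisporum$qualitative$basidia_spore_number  # 2
#' @export
load_taxa <- function(path = hebeloma_file("greenland_taxa.json")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$taxa) || length(raw$taxa) == 0L)
    stop("empty or malformed trait database: no taxa")
  recs <- lapply(raw$taxa, .validate_taxon)
  names(recs) <- vapply(recs, function(t) t$name, character(1))
  if (anyDuplicated(names(recs)))
    stop("duplicate species in trait database: ",
         paste(unique(names(recs)[duplicated(names(recs))]), collapse = ", "))
  class(recs) <- "taxon_db"
  recs
}

.check_interval <- function(x, what, taxon) {
  x <- unlist(x)
  if (length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop("malformed interval ", what, " for taxon ", taxon)
  as.numeric(x)
}

.validate_taxon <- function(t) {
  if (is.null(t$name)) stop("taxon without a name")
  # JSON null round-trips as NULL, NA or an empty list depending on writer
  if (length(t$subsection) != 1L || is.na(t$subsection)) t$subsection <- NULL
  if (!t$section %in% .sections)
    stop("unknown section ", sQuote(t$section), " for taxon ", t$name)
  if (!is.null(t$subsection) && !t$subsection %in% .subsections)
    stop("unknown subsection ", sQuote(t$subsection), " for taxon ", t$name)
  for (f in c("spore_mean_length_range", "spore_mean_width_range",
              "spore_mean_q_range", "lamellae_count_range"))
    t[[f]] <- .check_interval(t[[f]], f, t$name)
  for (f in c("length_range", "apex_range", "middle_range", "base_range",
              "ratio_am_range", "ratio_ab_range", "ratio_bm_range"))
    t$cystidia[[f]] <- .check_interval(t$cystidia[[f]], f, t$name)
  t$ornamentation <- parse_opd(t$ornamentation)
  t$perispore <- parse_opd(t$perispore)
  t$dextrinoidity <- parse_opd(t$dextrinoidity)
  q <- t$qualitative
  if (!q$cheilocystidia_form %in% .cheilo_forms)
    stop("unknown cheilocystidia_form for taxon ", t$name)
  if (!q$spore_shape_majority %in% .spore_shapes)
    stop("unknown spore_shape_majority for taxon ", t$name)
  if (!q$papilla %in% .papilla_levels)
    stop("unknown papilla level for taxon ", t$name)
  q$stem_width_range_cm <- .check_interval(q$stem_width_range_cm,
                                           "stem_width_range_cm", t$name)
  t$qualitative <- q
  if (!t$distribution_group %in% 1:5)
    stop("distribution_group outside 1-5 for taxon ", t$name)
  if (!t$strategy %in% c("specialist", "opportunist"))
    stop("unknown strategy for taxon ", t$name)
  t$hosts <- unlist(t$hosts)
  class(t) <- "taxon_record"
  t
}

#' @export
print.taxon_db <- function(x, ...) {
  cat(sprintf("Hebeloma trait database: %d species\n", length(x)))
  df <- as.data.frame(x)
  print(df[, c("species", "section", "distribution_group", "strategy",
               "n_collections")], row.names = FALSE)
  invisible(x)
}

#' @export
print.taxon_record <- function(x, ...) {
  cat(sprintf("Hebeloma %s (sect. %s%s)\n", x$name, x$section,
              if (!is.null(x$subsection)) paste0(", subsect. ", x$subsection) else ""))
  cat(sprintf("  spores on ave. %.1f-%.1f x %.1f-%.1f um, Q %.2f-%.2f\n",
              x$spore_mean_length_range[1], x$spore_mean_length_range[2],
              x$spore_mean_width_range[1], x$spore_mean_width_range[2],
              x$spore_mean_q_range[1], x$spore_mean_q_range[2]))
  cat(sprintf("  codes %s | %s | %s; L %d-%d\n",
              format(x$ornamentation), format(x$perispore),
              format(x$dextrinoidity),
              x$lamellae_count_range[1], x$lamellae_count_range[2]))
  cat(sprintf("  group %d (%s), %d collection(s)\n",
              x$distribution_group, x$strategy, x$n_collections))
  invisible(x)
}

#' @export
as.data.frame.taxon_db <- function(x, ...) {
  do.call(rbind, lapply(x, function(t) data.frame(
    species = t$name, section = t$section,
    subsection = if (is.null(t$subsection)) NA_character_ else t$subsection,
    mean_length_lo = t$spore_mean_length_range[1],
    mean_length_hi = t$spore_mean_length_range[2],
    mean_width_lo = t$spore_mean_width_range[1],
    mean_width_hi = t$spore_mean_width_range[2],
    lamellae_lo = t$lamellae_count_range[1],
    lamellae_hi = t$lamellae_count_range[2],
    distribution_group = t$distribution_group, strategy = t$strategy,
    n_collections = t$n_collections,
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Centroid specimen profile for a taxon
#'
#' Builds a [specimen_profile()] whose continuous traits sit at the
#' midpoints of the taxon's described ranges and whose categorical traits
#' equal the recorded states. Used to cross-validate the keys against the
#' descriptions.
#'
#' @param taxon A `taxon_record`.
#' @return A `specimen_profile`.
#' @examples
#' taxa <- load_taxa()
#' centroid_profile(taxa$grandisporum)$mean_length  # 15
#' @export
centroid_profile <- function(taxon) {
  if (!inherits(taxon, "taxon_record")) stop("not a taxon_record")
  need <- c("spore_mean_length_range", "spore_mean_width_range",
            "spore_mean_q_range", "lamellae_count_range")
  missing <- need[vapply(need, function(f) is.null(taxon[[f]]) ||
                           anyNA(taxon[[f]]), logical(1))]
  if (length(missing))
    stop("taxon ", taxon$name, " lacks key-relevant trait(s): ",
         paste(missing, collapse = ", "))
  mid <- function(iv) mean(iv)
  specimen_profile(
    mean_length = mid(taxon$spore_mean_length_range),
    mean_width = mid(taxon$spore_mean_width_range),
    mean_q = mid(taxon$spore_mean_q_range),
    lamellae_count = mid(taxon$lamellae_count_range),
    ornamentation = taxon$ornamentation,
    perispore = taxon$perispore,
    dextrinoidity = taxon$dextrinoidity,
    qualitative = taxon$qualitative,
    habitat_arctic_alpine = TRUE
  )
}

#' Path to a packaged data file
#'
#' @param ... File name components under the package's `extdata` directory.
#' @return A file path.
#' @export
hebeloma_file <- function(...) {
  p <- system.file("extdata", ..., package = "hebelomaGL", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged file not found: ", file.path(...))
  p
}
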