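# The occurrence catalogue: one row per voucher collection with database
# reference, voucher, species, ITS GenBank accession (with partial-ITS
# flags), decimal coordinates (west negative), elevation, date, collector,
# locality, host plants and the region under which the source files the
# collection.

.catalogue_cols <- c("db_ref", "voucher", "other_number", "species",
                     "its_accession", "its_partial", "latitude", "longitude",
                     "elevation_m", "date", "collector", "locality", "hosts",
                     "region_stated")

#' Load a collection catalogue
#'
#' Reads and validates a catalogue CSV. Validation: unique `db_ref`,
#' species restricted to `species_whitelist` when given, accessions
#' matching the GenBank pattern (two letters + six digits), `its_partial`
#' in `full`/`ITS1`/`ITS2`, and coordinates within the Greenland bounding
#' box when present. Errors name the offending row.
#'
#' @param path Path to a catalogue CSV; defaults to the packaged Greenland
#'   catalogue of 378 collections.
#' @param species_whitelist Optional character vector of accepted species
#'   epithets (e.g. `names(load_taxa())`).
#' @return A data frame of class `hebeloma_catalogue`.
#' @examples
#' cat378 <- load_catalogue()
#' nrow(cat378)  # 378
#' @export
load_catalogue <- function(path = hebeloma_file("greenland_catalogue.csv"),
                           species_whitelist = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(date = "character"))
  miss <- setdiff(.catalogue_cols, names(d))
  if (length(miss))
    stop("catalogue is missing column(s): ", paste(miss, collapse = ", "))
  d <- d[.catalogue_cols]
  dup <- d$db_ref[duplicated(d$db_ref)]
  if (length(dup))
    stop("duplicate db_ref in catalogue: ", paste(unique(dup), collapse = ", "))
  if (!is.null(species_whitelist)) {
    bad <- which(!d$species %in% species_whitelist)
    if (length(bad))
      stop("unknown species at row ", bad[1], ": ", sQuote(d$species[bad[1]]))
  }
  has_acc <- !is.na(d$its_accession) & nzchar(d$its_accession)
  ok <- grepl("^[A-Z]{2}\\d{6}(,\\s*[A-Z]{2}\\d{6})*$",
              d$its_accession[has_acc])
  if (any(!ok)) {
    r <- which(has_acc)[which(!ok)[1]]
    stop("malformed accession at row ", r, ": ", sQuote(d$its_accession[r]))
  }
  if (any(!d$its_partial %in% c("full", "ITS1", "ITS2")))
    stop("its_partial must be one of full, ITS1, ITS2")
  has_coord <- !is.na(d$latitude) & !is.na(d$longitude)
  if (any(has_coord))
    assign_region(d$latitude[has_coord], d$longitude[has_coord])  # bbox check
  d$date <- as.Date(ifelse(nzchar(d$date), d$date, NA))
  class(d) <- c("hebeloma_catalogue", "data.frame")
  d
}

#' Write a catalogue CSV
#'
#' Inverse of [load_catalogue()]; a write/read round trip preserves all
#' fields.
#'
#' @param catalogue A catalogue data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  d <- as.data.frame(catalogue)[.catalogue_cols]
  d$date <- ifelse(is.na(d$date), "", format(d$date))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.hebeloma_catalogue <- function(x, ...) {
  cat(sprintf("Hebeloma collection catalogue: %d records, %d species\n",
              nrow(x), length(unique(x$species))))
  cat(sprintf("  with coordinates: %d; partial ITS: %d\n",
              sum(!is.na(x$latitude)), sum(x$its_partial != "full")))
  invisible(x)
}

#' Collections per species
#'
#' @param catalogue A catalogue data frame.
#' @return Named integer vector, sorted by species name; sums to
#'   `nrow(catalogue)`.
#' @examples
#' counts <- count_by_species(load_catalogue())
#' counts[["colvinii"]]  # 5
#' @export
count_by_species <- function(catalogue) {
  if (!nrow(catalogue)) return(integer())
  tab <- table(catalogue$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Share of the catalogue belonging to one species
#'
#' Returns `100 * count / total` rounded half-up to one decimal, the
#' rounding that reproduces the published shares (e.g. 44/378 = 11.6).
#'
#' @param catalogue A catalogue data frame.
#' @param species Species epithet.
#' @return Percentage, one decimal.
#' @examples
#' species_share(load_catalogue(), "hiemale")  # 11.6
#' @export
species_share <- function(catalogue, species) {
  if (!nrow(catalogue)) stop("empty catalogue")
  n <- sum(catalogue$species == species)
  round_half_up(100 * n / nrow(catalogue), 1)
}

#' Round half away from zero
#'
#' `round()` in R rounds half to even; published shares use ordinary
#' half-up rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Count collections with only partial ITS sequences
#'
#' @param catalogue A catalogue data frame.
#' @return Integer count of records flagged ITS1-only or ITS2-only, with
#'   the per-flag breakdown as attribute `breakdown`.
#' @export
partial_its_count <- function(catalogue) {
  n1 <- sum(catalogue$its_partial == "ITS1")
  n2 <- sum(catalogue$its_partial == "ITS2")
  structure(n1 + n2, breakdown = c(ITS1 = n1, ITS2 = n2))
}
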