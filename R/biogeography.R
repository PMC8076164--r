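# Greenland biogeographic scheme: four regions (South below 62.20 deg N;
# North above 74 deg N; West/East between, split by the ice-sheet divide,
# approximated here by a configurable meridian) and the Low/High Arctic
# bioclimatic zones divided approximately along 70 deg N. Species are
# grouped 1-5 by the set of regions in which they have been collected.

#' Assign a collection to a Greenland region and bioclimatic zone
#'
#' Latitudes below 62.20 deg N are South Greenland, above 74 deg N North
#' Greenland; in between the side of the divide meridian decides West vs
#' East. Latitudes exactly on a boundary fall on the northern side. The
#' Low/High Arctic boundary is modelled as a single latitude (default 70 deg
#' N; the real line runs from central Disko Island to the Blosseville
#' Coast). The tiny Subarctic zone is botanically defined and never inferred
#' from coordinates: it is assigned only via `subarctic`.
#'
#' @param lat,lon Decimal degrees, west longitude negative. Vectorised.
#' @param divide_lon Meridian separating West from East Greenland between
#'   62.20 and 74 deg N (default -44).
#' @param zone_lat Low/High Arctic boundary latitude (default 70).
#' @param subarctic Logical vector (recycled): explicit site flag for the
#'   Subarctic zone.
#' @return A data frame with columns `region` ("South", "West", "North",
#'   "East"), `zone` ("Subarctic", "LowArctic", "HighArctic") and `basis`
#'   (the rule that fired).
#' @examples
#' assign_region(61.15, -45.42)  # Narsarsuaq: South, Low Arctic
#' assign_region(74.47, -21.0)   # Zackenberg: North, High Arctic
#' @export
assign_region <- function(lat, lon, divide_lon = -44, zone_lat = 70,
                          subarctic = FALSE) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  subarctic <- rep_len(subarctic, n)
  if (anyNA(lat) || anyNA(lon))
    stop("coordinates must not be missing; filter records without coordinates first")
  if (any(lat < 59 | lat > 84 | lon < -75 | lon > -10))
    stop("coordinate outside the Greenland bounding box (59-84 N, 75-10 W)")
  region <- ifelse(lat < 62.20, "South",
            ifelse(lat >= 74, "North",
            ifelse(lon < divide_lon, "West", "East")))
  basis <- ifelse(lat < 62.20, "lat < 62.20",
           ifelse(lat >= 74, "lat >= 74",
           ifelse(lon < divide_lon,
                  sprintf("62.20 <= lat < 74 and lon < %g", divide_lon),
                  sprintf("62.20 <= lat < 74 and lon >= %g", divide_lon))))
  zone <- ifelse(subarctic, "Subarctic",
          ifelse(lat >= zone_lat, "HighArctic", "LowArctic"))
  data.frame(region = region, zone = zone, basis = basis,
             stringsAsFactors = FALSE)
}

#' Distribution group from a set of occupied regions
#'
#' Group 1: South only. Group 2: South and West only. Group 3: South and
#' East, no North. Group 4: South and North (all of Greenland). Group 5:
#' never collected in South Greenland.
#'
#' @param region_set Character vector of single-letter region codes drawn
#'   from `S`, `W`, `N`, `E` (a set; duplicates ignored), or a list of such
#'   vectors.
#' @return Integer group(s) 1-5.
#' @examples
#' assign_group(c("S", "W"))       # 2
#' assign_group(c("W", "E"))       # 5
#' assign_group(c("S", "W", "N", "E"))  # 4
#' @export
assign_group <- function(region_set) {
  if (is.list(region_set))
    return(vapply(region_set, assign_group, integer(1)))
  s <- unique(region_set)
  if (!length(s)) stop("empty region set")
  bad <- setdiff(s, c("S", "W", "N", "E"))
  if (length(bad)) stop("unknown region code: ", paste(bad, collapse = ", "))
  if (!"S" %in% s) return(5L)
  if ("N" %in% s) return(4L)
  if ("E" %in% s) return(3L)
  if ("W" %in% s) return(2L)
  1L
}

.region_letter <- c(South = "S", West = "W", North = "N", East = "E")

#' Tabulate species by distribution group
#'
#' Computes each species' occupied region set from its collections, assigns
#' the distribution group and sums collection counts per species, in the
#' layout of the distribution-group table. When the catalogue has a
#' `region_stated` column (the region under which the source files the
#' collection), it takes precedence over the coordinate-derived region;
#' records whose stated and computed regions disagree are flagged in the
#' `mismatches` attribute. Records without coordinates or stated region are
#' excluded from region-set derivation (their counts still appear).
#'
#' @param catalogue A catalogue data frame (see [load_catalogue()]).
#' @param taxa Optional `taxon_db`; when given, the table carries each
#'   species' recorded strategy and the stored group for comparison.
#' @param divide_lon,zone_lat Passed to [assign_region()].
#' @return A data frame (class `group_table`) with one row per species:
#'   `species`, `group`, `region_set`, `n_collections`, and when `taxa` is
#'   given `strategy` and `stored_group`; plus attributes `total` and
#'   `mismatches`.
#' @export
tabulate_groups <- function(catalogue, taxa = NULL, divide_lon = -44,
                            zone_lat = 70) {
  if (!nrow(catalogue)) {
    out <- data.frame(species = character(), group = integer(),
                      region_set = character(), n_collections = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    class(out) <- c("group_table", "data.frame")
    return(out)
  }
  has_coord <- !is.na(catalogue$latitude) & !is.na(catalogue$longitude)
  computed <- rep(NA_character_, nrow(catalogue))
  if (any(has_coord))
    computed[has_coord] <- .region_letter[assign_region(
      catalogue$latitude[has_coord], catalogue$longitude[has_coord],
      divide_lon = divide_lon, zone_lat = zone_lat)$region]
  stated <- if ("region_stated" %in% names(catalogue)) {
    s <- as.character(catalogue$region_stated)
    s[!s %in% c("S", "W", "N", "E")] <- NA_character_
    s
  } else rep(NA_character_, nrow(catalogue))
  region <- ifelse(is.na(stated), computed, stated)
  mism <- which(!is.na(stated) & !is.na(computed) & stated != computed)
  species <- sort(unique(catalogue$species))
  rows <- lapply(species, function(sp) {
    i <- catalogue$species == sp
    rs <- sort(unique(region[i & !is.na(region)]))
    data.frame(species = sp,
               group = if (length(rs)) assign_group(rs) else NA_integer_,
               region_set = paste(rs, collapse = ""),
               n_collections = sum(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(taxa)) {
    out$strategy <- vapply(out$species, function(sp)
      if (!is.null(taxa[[sp]])) taxa[[sp]]$strategy else NA_character_,
      character(1))
    out$stored_group <- vapply(out$species, function(sp)
      if (!is.null(taxa[[sp]])) taxa[[sp]]$distribution_group else NA_integer_,
      integer(1))
  }
  out <- out[order(out$group, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$n_collections)
  attr(out, "mismatches") <- if (length(mism))
    catalogue[mism, c("db_ref", "species", "latitude", "longitude",
                      "region_stated")] else NULL
  class(out) <- c("group_table", "data.frame")
  out
}

#' @export
print.group_table <- function(x, ...) {
  for (g in sort(unique(x$group))) {
    sub <- x[!is.na(x$group) & x$group == g, , drop = FALSE]
    cat(sprintf("Group %d (%d species, %d collections)\n", g, nrow(sub),
                sum(sub$n_collections)))
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  H. %-18s %3d  %s\n", sub$species[i],
                  sub$n_collections[i], sub$region_set[i]))
  }
  cat("Total collections:", attr(x, "total"), "\n")
  m <- attr(x, "mismatches")
  if (!is.null(m))
    cat(sprintf("(%d record(s) use the stated region over coordinates)\n",
                nrow(m)))
  invisible(x)
}

#' Species recorded in the Subarctic zone of southernmost Greenland
#'
#' Counts distinct species with at least one collection south of the
#' latitude cutoff used for the Subarctic analysis.
#'
#' @param catalogue A catalogue data frame.
#' @param lat_cutoff Latitude in degrees north (default 61.25).
#' @return Integer count; the species names are attached as attribute
#'   `species`.
#' @export
subarctic_species_count <- function(catalogue, lat_cutoff = 61.25) {
  i <- !is.na(catalogue$latitude) & catalogue$latitude < lat_cutoff
  sp <- sort(unique(catalogue$species[i]))
  structure(length(sp), species = sp)
}
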