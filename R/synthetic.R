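# Seeded synthetic data with the statistical structure the analysis
# assumes: specimens whose collection means are drawn inside each species'
# described "on ave." intervals (interval = +/- 2 SD envelope of the
# collection mean), catalogues whose collections are placed around the five
# main Greenland localities consistently with each species' distribution
# group, and toy alignments with engineered private and shared ITS
# variants.

#' Simulation configuration
#'
#' @param seed Integer seed; fixes all outputs bit-for-bit.
#' @param n_spores_per_specimen Spores measured per synthetic collection
#'   (default 50, the protocol minimum).
#' @param n_cystidia Full cystidium quadruples per collection (default 20).
#' @param measurement_noise Relative SD of individual measurements around
#'   the collection mean (default 0.05).
#' @param specimens_per_species Collections per species in a synthetic
#'   catalogue (default 4).
#' @param coordinate_jitter SD in degrees of the scatter around a site
#'   (default 0.05; small enough never to move a site across a region
#'   boundary).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_spores_per_specimen = 50L,
                       n_cystidia = 20L, measurement_noise = 0.05,
                       specimens_per_species = 4L,
                       coordinate_jitter = 0.05) {
  stopifnot(n_spores_per_specimen >= 1, n_cystidia >= 1,
            specimens_per_species >= 1, measurement_noise >= 0,
            coordinate_jitter >= 0)
  structure(list(seed = as.integer(seed),
                 n_spores_per_specimen = as.integer(n_spores_per_specimen),
                 n_cystidia = as.integer(n_cystidia),
                 measurement_noise = measurement_noise,
                 specimens_per_species = as.integer(specimens_per_species),
                 coordinate_jitter = coordinate_jitter),
            class = "sim_config")
}

# truncated normal draw by inverse-CDF; degenerate interval returns its value
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0 || lo == hi) return(rep(max(lo, min(hi, mean)), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# collection mean drawn so the described interval is a +/- 2 SD envelope
.draw_mean <- function(iv) {
  .rtruncnorm(1, mean(iv), (iv[2] - iv[1]) / 4, iv[1], iv[2])
}

#' Generate one synthetic specimen of a species
#'
#' Draws a collection mean for spore length and width inside the species'
#' "on ave." interval (centre at the midpoint, SD a quarter of the interval
#' so the interval is a +/- 2 SD envelope), then individual spores around
#' that mean with relative SD `measurement_noise`. Cystidia are drawn the
#' same way from the cystidium ranges. Ordinal codes copy the species'
#' class set, with parenthetical (rare) classes included with probability
#' 0.15; qualitative characters are copied verbatim.
#'
#' @param taxon A `taxon_record`.
#' @param config A [sim_config()]; its `seed` fixes the draw.
#' @return A list of class `synthetic_specimen`: `species`, `spores` (data
#'   frame length/width), `cystidia` (data frame length/apex/middle/base),
#'   `lamellae_count`, and `profile` (a [specimen_profile()] built from the
#'   summarised measurements).
#' @export
generate_specimen <- function(taxon, config = sim_config()) {
  if (!inherits(taxon, "taxon_record")) stop("not a taxon_record")
  for (f in c("spore_mean_length_range", "spore_mean_width_range",
              "lamellae_count_range"))
    if (is.null(taxon[[f]])) stop("taxon ", taxon$name, " lacks ", f)
  set.seed(config$seed)
  n <- config$n_spores_per_specimen
  noise <- config$measurement_noise
  ml <- .draw_mean(taxon$spore_mean_length_range)
  mw <- .draw_mean(taxon$spore_mean_width_range)
  spores <- data.frame(
    length = .rtruncnorm(n, ml, noise * ml, lo = 0.2 * ml),
    width = .rtruncnorm(n, mw, noise * mw, lo = 0.2 * mw))
  nc <- config$n_cystidia
  cl <- .draw_mean(taxon$cystidia$length_range)
  ca <- .draw_mean(taxon$cystidia$apex_range)
  cm <- .draw_mean(taxon$cystidia$middle_range)
  cb <- .draw_mean(taxon$cystidia$base_range)
  cystidia <- data.frame(
    length = .rtruncnorm(nc, cl, noise * cl, lo = 0.2 * cl),
    apex = .rtruncnorm(nc, ca, noise * ca, lo = 0.2 * ca),
    middle = .rtruncnorm(nc, cm, noise * cm, lo = 0.2 * cm),
    base = .rtruncnorm(nc, cb, noise * cb, lo = 0.2 * cb))
  L <- round(.rtruncnorm(1, mean(taxon$lamellae_count_range),
                         diff(taxon$lamellae_count_range) / 4,
                         taxon$lamellae_count_range[1],
                         taxon$lamellae_count_range[2]))
  draw_codes <- function(codes) {
    keep <- !codes$parenthetical | stats::runif(nrow(codes)) < 0.15
    if (!any(keep)) keep <- !codes$parenthetical
    out <- codes[keep, , drop = FALSE]
    attr(out, "scale") <- attr(codes, "scale")
    class(out) <- c("opd_codes", "data.frame")
    out
  }
  sp_sum <- summarize_spores(spores$length, spores$width)
  cy_sum <- summarize_cheilocystidia(cystidia$length, cystidia$apex,
                                     cystidia$middle, cystidia$base)
  prof <- specimen_profile(
    lamellae_count = L,
    ornamentation = draw_codes(taxon$ornamentation),
    perispore = draw_codes(taxon$perispore),
    dextrinoidity = draw_codes(taxon$dextrinoidity),
    qualitative = taxon$qualitative,
    spores = sp_sum, cystidia = cy_sum,
    habitat_arctic_alpine = TRUE)
  structure(list(species = taxon$name, spores = spores, cystidia = cystidia,
                 lamellae_count = L, profile = prof),
            class = "synthetic_specimen")
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf("Synthetic specimen of Hebeloma %s (%d spores, %d cystidia, L = %d)\n",
              x$species, nrow(x$spores), nrow(x$cystidia), x$lamellae_count))
  invisible(x)
}

# the five main collecting localities, one per accessible region (South has
# two; Jameson Land sits east of the divide below 74 N, Zackenberg above)
.sim_sites <- data.frame(
  site = c("Narsarsuaq", "Paamiut", "Kangerlussuaq", "Zackenberg",
           "Jameson Land"),
  lat = c(61.15, 62.01, 67.06, 74.47, 70.76),
  lon = c(-45.42, -49.40, -50.46, -21.00, -22.65),
  region = c("S", "S", "W", "N", "E"),
  stringsAsFactors = FALSE)

.group_regions <- list(`1` = "S", `2` = c("S", "W"), `3` = c("S", "W", "E"),
                       `4` = c("S", "W", "N", "E"), `5` = c("N", "E"))

#' Generate a synthetic collection catalogue
#'
#' Places each species' synthetic collections only at sites within the
#' regions its distribution group allows, covering every required region at
#' least once, so [tabulate_groups()] on the result recovers every species'
#' stored group exactly.
#'
#' @param taxa A `taxon_db`.
#' @param config A [sim_config()]; `specimens_per_species` collections are
#'   generated per species (at least one per required region, so the
#'   effective number may be larger for wide-ranging groups).
#' @return A `hebeloma_catalogue` data frame.
#' @export
generate_catalogue <- function(taxa, config = sim_config()) {
  set.seed(config$seed)
  rows <- list(); serial <- 0L
  for (t in taxa) {
    regions <- .group_regions[[as.character(t$distribution_group)]]
    n <- max(config$specimens_per_species, length(regions))
    reg_seq <- rep_len(regions, n)
    for (r in reg_seq) {
      serial <- serial + 1L
      cand <- .sim_sites[.sim_sites$region == r, , drop = FALSE]
      site <- cand[sample.int(nrow(cand), 1L), ]
      lat <- site$lat + stats::rnorm(1, 0, config$coordinate_jitter)
      lon <- site$lon + stats::rnorm(1, 0, config$coordinate_jitter)
      # jitter must never cross a region boundary
      lat <- switch(r, S = min(lat, 62.19), N = max(lat, 74.01),
                    W = max(min(lat, 73.9), 62.3),
                    E = max(min(lat, 73.9), 62.3))
      rows[[serial]] <- data.frame(
        db_ref = sprintf("SYN%05d", serial),
        voucher = sprintf("SYN-F-%05d", serial),
        other_number = "",
        species = t$name,
        its_accession = sprintf("SY%06d", serial),
        its_partial = "full",
        latitude = round(lat, 4), longitude = round(lon, 4),
        elevation_m = round(stats::runif(1, 0, 400)),
        date = as.Date(sprintf("2020-08-%02d", sample.int(28, 1L))),
        collector = "simulated",
        locality = site$site,
        hosts = if (length(t$hosts)) sample(t$hosts, 1L) else "",
        region_stated = r,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hebeloma_catalogue", "data.frame")
  out
}

#' Generate a toy aligned ITS data set with engineered variant structure
#'
#' Builds an alignment in which every species has one private variant
#' carrying `n_per_species` sequences, and `n_shared_variants` additional
#' variants are each shared by a pair of species (one sequence from each).
#' The returned manifest is the ground truth against which
#' [collapse_variants()] and [shared_variant_table()] can be checked.
#'
#' @param n_species Number of species labels (>= 1).
#' @param n_per_species Sequences in each species' private variant (>= 1).
#' @param n_shared_variants Number of engineered two-species shared
#'   variants (>= 0; requires `n_species >= 2` when positive).
#' @param seed Integer seed.
#' @param alignment_length Number of alignment columns (default 80; must
#'   exceed `n_species + n_shared_variants`).
#' @return A list: `seqs` (named character vector), `labels` (data frame
#'   id/species/region) and `manifest` (list with `n_classes`,
#'   `shared_members` per species, `private_members` per species).
#' @export
generate_toy_alignment <- function(n_species = 2, n_per_species = 3,
                                   n_shared_variants = 1, seed = 1L,
                                   alignment_length = 80L) {
  stopifnot(n_species >= 1, n_per_species >= 1, n_shared_variants >= 0)
  if (n_shared_variants > 0 && n_species < 2)
    stop("shared variants need at least two species")
  if (alignment_length <= n_species + n_shared_variants)
    stop("alignment_length must exceed n_species + n_shared_variants")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, alignment_length, replace = TRUE)
  mutate_at <- function(pos) {
    s <- backbone
    s[pos] <- setdiff(bases, s[pos])[1]
    paste(s, collapse = "")
  }
  species <- sprintf("sp%02d", seq_len(n_species))
  seqs <- character(); labs <- list()
  add <- function(id, sp, seq_str) {
    seqs[[id]] <<- seq_str
    labs[[length(labs) + 1L]] <<- data.frame(
      id = id, species = sp,
      region = if (length(labs) %% 2L == 0L) "Greenland" else "elsewhere",
      stringsAsFactors = FALSE)
  }
  private <- stats::setNames(vector("list", n_species), species)
  for (i in seq_len(n_species)) {
    v <- mutate_at(i)
    ids <- sprintf("%s_p%02d", species[i], seq_len(n_per_species))
    for (id in ids) add(id, species[i], v)
    private[[species[i]]] <- ids
  }
  shared <- stats::setNames(rep(0L, n_species), species)
  for (j in seq_len(n_shared_variants)) {
    v <- mutate_at(n_species + j)
    a <- species[(j - 1L) %% n_species + 1L]
    b <- species[j %% n_species + 1L]
    add(sprintf("%s_s%02d", a, j), a, v)
    add(sprintf("%s_s%02d", b, j), b, v)
    shared[a] <- shared[a] + 1L
    shared[b] <- shared[b] + 1L
  }
  list(seqs = seqs, labels = do.call(rbind, labs),
       manifest = list(n_classes = n_species + n_shared_variants,
                       private_members = private,
                       shared_members_per_species = shared))
}
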