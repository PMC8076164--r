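# Dichotomous key engine. The four printed keys (section key plus species
# keys for sections Hebeloma, Denudata and Velutipes) are stored as
# declarative decision trees: each couplet has leads carrying a predicate
# tree over specimen-profile fields and an outcome (taxon, another couplet,
# or an entry point in another key). Evaluation is three-valued: a
# predicate over an unrecorded trait is `unknown` (NA), NA propagates
# through AND/OR/NOT by Kleene semantics, and at an undecidable couplet the
# engine follows every lead and returns the union of reachable species as a
# candidate set.

#' Construct a specimen profile
#'
#' A specimen profile carries the characters the keys consult: collection
#' mean spore dimensions and Q, lamellae count (L), the O/P/D ordinal code
#' sets, and the qualitative characters (veil, cap coloring, cheilocystidium
#' form, spore shape majority, papilla, ...). Any field may be omitted
#' (`NULL`), meaning unknown; the key engine then explores both leads of any
#' couplet that depends on it.
#'
#' @param mean_length,mean_width,mean_q Collection means (micrometres;
#'   Q dimensionless), or `NULL`.
#' @param lamellae_count Number of full-length lamellae, or `NULL`.
#' @param ornamentation,perispore,dextrinoidity `opd_codes` objects (see
#'   [parse_opd()]) or code strings, or `NULL`.
#' @param qualitative Named list of qualitative characters
#'   (`veil_present`, `cap_bicolored`, `pileus_pubescent`,
#'   `cheilocystidia_form`, `spore_shape_majority`, `papilla`,
#'   `basidia_spore_number`, `apical_wall_thickening`, `cap_center_pale`,
#'   `cap_dark_reddish`, `cap_overhanging`, `stem_width_range_cm`); missing
#'   entries are unknown.
#' @param spores,cystidia Optional [summarize_spores()] /
#'   [summarize_cheilocystidia()] results; when given, mean dimensions are
#'   taken from them unless passed explicitly.
#' @param habitat_arctic_alpine Logical; Greenland collections are
#'   arctic-alpine by default.
#' @return An object of class `specimen_profile`.
#' @export
specimen_profile <- function(mean_length = NULL, mean_width = NULL,
                             mean_q = NULL, lamellae_count = NULL,
                             ornamentation = NULL, perispore = NULL,
                             dextrinoidity = NULL, qualitative = list(),
                             spores = NULL, cystidia = NULL,
                             habitat_arctic_alpine = TRUE) {
  if (!is.null(spores)) {
    if (is.null(mean_length)) mean_length <- spores$mean_length
    if (is.null(mean_width)) mean_width <- spores$mean_width
    if (is.null(mean_q)) mean_q <- spores$mean_q
  }
  as_codes <- function(x) {
    if (is.null(x) || inherits(x, "opd_codes")) x else parse_opd(x)
  }
  num_ok <- function(x, what) {
    if (!is.null(x) && (!is.numeric(x) || is.na(x) || x <= 0))
      stop(what, " must be a positive number or NULL")
    x
  }
  p <- list(
    mean_length = num_ok(mean_length, "mean_length"),
    mean_width = num_ok(mean_width, "mean_width"),
    mean_q = num_ok(mean_q, "mean_q"),
    lamellae_count = num_ok(lamellae_count, "lamellae_count"),
    ornamentation = as_codes(ornamentation),
    perispore = as_codes(perispore),
    dextrinoidity = as_codes(dextrinoidity),
    qualitative = qualitative,
    spores = spores, cystidia = cystidia,
    habitat_arctic_alpine = habitat_arctic_alpine
  )
  class(p) <- "specimen_profile"
  p
}

#' @export
print.specimen_profile <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "?" else format(v, digits = 3)
  cat("Specimen profile\n")
  cat(sprintf("  spores on ave. %s x %s um, Q %s; L %s\n",
              fmt(x$mean_length), fmt(x$mean_width), fmt(x$mean_q),
              fmt(x$lamellae_count)))
  cat(sprintf("  codes: %s | %s | %s\n",
              if (is.null(x$ornamentation)) "?" else format(x$ornamentation),
              if (is.null(x$perispore)) "?" else format(x$perispore),
              if (is.null(x$dextrinoidity)) "?" else format(x$dextrinoidity)))
  known <- names(x$qualitative)[!vapply(x$qualitative, is.null, logical(1))]
  cat("  qualitative recorded:",
      if (length(known)) paste(known, collapse = ", ") else "none", "\n")
  invisible(x)
}

# ---- Key loading and structural validation ---------------------------------

#' Load the identification keys
#'
#' Reads the packaged key file (or a user file with the same schema) and
#' verifies its structure: every referenced couplet and key exists, the
#' decision graph is acyclic, and every terminal species is reachable from
#' couplet 1 of the entry key.
#'
#' @param path Path to a key-definition JSON file; defaults to the packaged
#'   Greenland keys.
#' @return An object of class `key_set`.
#' @examples
#' keys <- load_keys()
#' length(key_terminals(keys))  # 28 species
#' @export
load_keys <- function(path = hebeloma_file("greenland_keys.json")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ks <- structure(list(entry = raw$entry, keys = raw$keys), class = "key_set")
  .validate_key_structure(ks)
  ks
}

.lead_outcome <- function(lead) lead$outcome

.validate_key_structure <- function(ks) {
  for (kn in names(ks$keys)) {
    k <- ks$keys[[kn]]
    for (cn in names(k$couplets)) {
      for (lead in k$couplets[[cn]]) {
        out <- .lead_outcome(lead)
        if (!is.null(out$key)) {
          if (is.null(ks$keys[[out$key]]))
            stop("key ", kn, " couplet ", cn, " points to unknown key ",
                 sQuote(out$key))
          tgt <- as.character(if (is.null(out$couplet)) 1 else out$couplet)
          if (is.null(ks$keys[[out$key]]$couplets[[tgt]]))
            stop("key ", kn, " couplet ", cn,
                 " points to dangling couplet ", tgt, " of key ", out$key)
        } else if (!is.null(out$couplet)) {
          if (is.null(k$couplets[[as.character(out$couplet)]]))
            stop("key ", kn, " couplet ", cn,
                 " points to dangling couplet ", out$couplet)
        } else if (is.null(out$taxon)) {
          stop("key ", kn, " couplet ", cn, " has a lead with no outcome")
        }
      }
    }
  }
  # acyclicity via DFS with colouring over (key, couplet) nodes
  state <- new.env(parent = emptyenv())
  visit <- function(kn, cn) {
    id <- paste(kn, cn, sep = ":")
    st <- get0(id, envir = state, ifnotfound = 0L)
    if (st == 1L) stop("cycle detected in keys at ", id)
    if (st == 2L) return(invisible())
    assign(id, 1L, envir = state)
    for (lead in ks$keys[[kn]]$couplets[[cn]]) {
      out <- .lead_outcome(lead)
      if (!is.null(out$key))
        visit(out$key, as.character(if (is.null(out$couplet)) 1 else out$couplet))
      else if (!is.null(out$couplet)) visit(kn, as.character(out$couplet))
    }
    assign(id, 2L, envir = state)
    invisible()
  }
  for (kn in names(ks$keys)) for (cn in names(ks$keys[[kn]]$couplets))
    visit(kn, cn)
  # reachability of every terminal from the entry key
  all_term <- key_terminals(ks)
  reach <- key_terminals(ks, ks$entry, within_key = FALSE)
  miss <- setdiff(all_term, reach)
  if (length(miss))
    stop("taxa unreachable from the entry key: ", paste(miss, collapse = ", "))
  invisible(ks)
}

#' Terminal species of a key
#'
#' @param keys A `key_set`.
#' @param key Key name; default all keys pooled. For a single key, only
#'   terminals reachable from its couplet 1 without leaving the key are
#'   counted (cross-key outcomes are entry points, not terminals of that
#'   key).
#' @param within_key Logical; when `TRUE` (default for a single named key),
#'   traversal does not follow outcomes into other keys.
#' @return Character vector of distinct species names.
#' @export
key_terminals <- function(keys, key = NULL, within_key = !is.null(key)) {
  start <- if (is.null(key)) {
    unlist(lapply(names(keys$keys), function(kn)
      paste(kn, names(keys$keys[[kn]]$couplets), sep = ":")))
  } else paste(key, "1", sep = ":")
  seen <- character(); taxa <- character()
  stack <- start
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    parts <- strsplit(id, ":", fixed = TRUE)[[1]]
    for (lead in keys$keys[[parts[1]]]$couplets[[parts[2]]]) {
      out <- .lead_outcome(lead)
      if (!is.null(out$taxon)) taxa <- c(taxa, out$taxon)
      else if (!is.null(out$key)) {
        if (!within_key)
          stack <- c(stack, paste(out$key,
                                  if (is.null(out$couplet)) 1 else out$couplet,
                                  sep = ":"))
      } else stack <- c(stack, paste(parts[1], out$couplet, sep = ":"))
    }
  }
  sort(unique(taxa))
}

#' @export
print.key_set <- function(x, ...) {
  cat("Identification keys (entry:", x$entry, ")\n")
  for (kn in names(x$keys))
    cat(sprintf("  %-10s %2d couplets, %2d terminal species within key\n",
                kn, length(x$keys[[kn]]$couplets),
                length(key_terminals(x, kn))))
  cat("  distinct species overall:", length(key_terminals(x)), "\n")
  invisible(x)
}

# ---- Three-valued predicate evaluation -------------------------------------

#' Evaluate a key predicate against a specimen profile
#'
#' Returns `TRUE`, `FALSE` or `NA` (unknown). Missing profile fields give
#' `NA`; `NA` propagates through AND/OR/NOT with Kleene semantics (e.g.
#' `FALSE AND NA` is `FALSE`, `TRUE AND NA` is `NA`).
#'
#' @param pred A predicate tree (a list, as stored in the key file).
#' @param profile A [specimen_profile()].
#' @return Logical scalar, possibly `NA`.
#' @export
evaluate_predicate <- function(pred, profile) {
  .eval_pred(pred, profile)$value
}

.kleene_and <- function(vals) {
  if (any(vapply(vals, isFALSE, logical(1)))) return(FALSE)
  if (any(vapply(vals, is.na, logical(1)))) return(NA)
  TRUE
}
.kleene_or <- function(vals) {
  if (any(vapply(vals, isTRUE, logical(1)))) return(TRUE)
  if (any(vapply(vals, is.na, logical(1)))) return(NA)
  FALSE
}

.num_fields <- c("mean_length", "mean_width", "mean_q", "lamellae_count",
                 "stem_width")
.ord_scales <- c("ornamentation", "perispore", "dextrinoidity")

# returns list(value = TRUE/FALSE/NA, unknown = character vector of the
# profile fields whose absence made the value NA)
.eval_pred <- function(pred, profile) {
  if (is.null(pred)) stop("NULL predicate cannot be evaluated directly")
  switch(pred$type,
    num = {
      if (!pred$field %in% .num_fields)
        stop("predicate references undefined numeric field ",
             sQuote(pred$field))
      v <- if (pred$field == "stem_width") {
        sw <- profile$qualitative$stem_width_range_cm
        if (is.null(sw)) NULL else mean(unlist(sw))
      } else profile[[pred$field]]
      if (is.null(v) || is.na(v))
        return(list(value = NA, unknown = pred$field))
      r <- switch(pred$op,
                  "<" = v < pred$value, "<=" = v <= pred$value,
                  ">" = v > pred$value, ">=" = v >= pred$value,
                  "==" = v == pred$value,
                  stop("unknown comparison operator ", sQuote(pred$op)))
      list(value = r, unknown = character())
    },
    ord = {
      if (!pred$scale %in% .ord_scales)
        stop("predicate references undefined ordinal scale ",
             sQuote(pred$scale))
      codes <- profile[[pred$scale]]
      if (is.null(codes)) return(list(value = NA, unknown = pred$scale))
      mode <- if (is.null(pred$mode)) "many" else pred$mode
      r <- if (mode == "has") opd_has(codes, pred$class)
           else opd_many(codes, pred$class)
      list(value = r, unknown = character())
    },
    qual = {
      v <- if (pred$field == "habitat_arctic_alpine")
        profile$habitat_arctic_alpine else profile$qualitative[[pred$field]]
      if (is.null(v) || (length(v) == 1L && is.na(v)))
        return(list(value = NA, unknown = pred$field))
      want <- unlist(pred$value)
      list(value = v %in% want, unknown = character())
    },
    "not" = {
      r <- .eval_pred(pred$arg, profile)
      list(value = if (is.na(r$value)) NA else !r$value, unknown = r$unknown)
    },
    "and" = {
      rs <- lapply(pred$args, .eval_pred, profile = profile)
      v <- .kleene_and(lapply(rs, `[[`, "value"))
      list(value = v,
           unknown = if (is.na(v)) unique(unlist(lapply(rs, `[[`, "unknown")))
                     else character())
    },
    "or" = {
      rs <- lapply(pred$args, .eval_pred, profile = profile)
      v <- .kleene_or(lapply(rs, `[[`, "value"))
      list(value = v,
           unknown = if (is.na(v)) unique(unlist(lapply(rs, `[[`, "unknown")))
                     else character())
    },
    stop("unknown predicate type ", sQuote(pred$type))
  )
}

# lead values at a couplet; a NULL predicate is the verbal alternative and
# takes the Kleene complement of the disjunction of the explicit leads
.couplet_lead_values <- function(leads, profile) {
  vals <- vector("list", length(leads))
  unks <- vector("list", length(leads))
  explicit <- !vapply(leads, function(l) is.null(l$predicate), logical(1))
  for (i in seq_along(leads)) {
    if (explicit[i]) {
      r <- .eval_pred(leads[[i]]$predicate, profile)
      vals[[i]] <- r$value; unks[[i]] <- r$unknown
    }
  }
  if (any(!explicit)) {
    other <- .kleene_or(vals[explicit])
    for (i in which(!explicit)) {
      vals[[i]] <- if (is.na(other)) NA else !other
      unks[[i]] <- unique(unlist(unks[explicit]))
    }
  }
  list(values = vals, unknown = unks)
}

# ---- Identification ---------------------------------------------------------

#' Identify a specimen through the keys
#'
#' Traverses the keys from couplet 1 of the entry key. At each couplet the
#' lead whose predicate is `TRUE` is followed; if no lead is decidable
#' (unknown traits) every lead compatible with the profile is followed and
#' the union of reachable species is returned as a candidate set. A couplet
#' at which every lead is plainly `FALSE` (a profile outside the key's
#' assumptions) is recorded as a conflict and all leads are followed.
#'
#' @param profile A [specimen_profile()].
#' @param keys A `key_set` from [load_keys()].
#' @param entry_key Name of the key to start in (default the key set's
#'   entry, the section key).
#' @return An object of class `identification`: list with `taxa` (character
#'   candidate set), `path` (data frame of the deterministic traversal),
#'   `indeterminate_traits`, `conflicts` (couplets where no lead held) and
#'   `visited` (all couplets explored).
#' @examples
#' keys <- load_keys()
#' taxa <- load_taxa()
#' identify_specimen(centroid_profile(taxa$grandisporum), keys)$taxa
#' @export
identify_specimen <- function(profile, keys, entry_key = keys$entry) {
  if (!inherits(profile, "specimen_profile")) stop("not a specimen_profile")
  res <- new.env(parent = emptyenv())
  res$taxa <- character(); res$unknown <- character()
  res$conflicts <- character(); res$visited <- character()
  res$path <- list(); res$deterministic <- TRUE
  walk <- function(kn, cn) {
    id <- paste(kn, cn, sep = ":")
    if (id %in% res$visited) return(invisible())
    res$visited <- c(res$visited, id)
    leads <- keys$keys[[kn]]$couplets[[cn]]
    lv <- .couplet_lead_values(leads, profile)
    vals <- lv$values
    # leads are read in printed order: follow the first TRUE lead, but any
    # undecidable (NA) lead encountered before it must be explored too
    first_true <- which(vapply(vals, isTRUE, logical(1)))[1]
    nas <- which(vapply(vals, is.na, logical(1)))
    if (!is.na(first_true)) {
      follow <- c(nas[nas < first_true], first_true)
    } else if (length(nas)) {
      follow <- nas
    } else {
      follow <- seq_along(leads)
      res$conflicts <- c(res$conflicts, id)
    }
    if (length(follow) > 1L || is.na(first_true)) {
      if (length(nas))
        res$unknown <- unique(c(res$unknown,
                                unlist(lv$unknown[intersect(follow, nas)])))
      if (length(follow) > 1L) res$deterministic <- FALSE
    }
    if (length(follow) == 1L && res$deterministic)
      res$path[[length(res$path) + 1L]] <-
        data.frame(key = kn, couplet = as.integer(cn), lead = follow,
                   stringsAsFactors = FALSE)
    for (i in follow) {
      out <- .lead_outcome(leads[[i]])
      if (!is.null(out$taxon)) res$taxa <- unique(c(res$taxa, out$taxon))
      else if (!is.null(out$key))
        walk(out$key, as.character(if (is.null(out$couplet)) 1 else out$couplet))
      else walk(kn, as.character(out$couplet))
    }
    invisible()
  }
  walk(entry_key, "1")
  out <- list(
    taxa = sort(res$taxa),
    path = if (length(res$path)) do.call(rbind, res$path) else
      data.frame(key = character(), couplet = integer(), lead = integer()),
    indeterminate_traits = sort(res$unknown),
    conflicts = res$conflicts,
    visited = res$visited
  )
  class(out) <- "identification"
  out
}

#' @export
print.identification <- function(x, ...) {
  if (length(x$taxa) == 1L) {
    cat("Identified as: Hebeloma", x$taxa, "\n")
  } else {
    cat(sprintf("Candidate set (%d species): %s\n", length(x$taxa),
                paste(x$taxa, collapse = ", ")))
    if (length(x$indeterminate_traits))
      cat("  unresolved traits:",
          paste(x$indeterminate_traits, collapse = ", "), "\n")
  }
  if (length(x$conflicts))
    cat("  conflicts (no lead satisfied) at:",
        paste(x$conflicts, collapse = ", "), "\n")
  if (nrow(x$path)) {
    cat("  path:", paste(sprintf("%s[%d]:%d", x$path$key, x$path$couplet,
                                 x$path$lead), collapse = " -> "), "\n")
  }
  invisible(x)
}

# ---- Key x trait-database cross-validation ---------------------------------

.field_interval <- function(taxon, field) {
  switch(field,
    mean_length = taxon$spore_mean_length_range,
    mean_width = taxon$spore_mean_width_range,
    mean_q = taxon$spore_mean_q_range,
    lamellae_count = taxon$lamellae_count_range,
    stem_width = taxon$qualitative$stem_width_range_cm,
    NULL)
}

.collect_num_fields <- function(pred) {
  if (is.null(pred)) return(character())
  switch(pred$type,
    num = pred$field,
    "not" = .collect_num_fields(pred$arg),
    "and" = unique(unlist(lapply(pred$args, .collect_num_fields))),
    "or" = unique(unlist(lapply(pred$args, .collect_num_fields))),
    character())
}

#' Cross-validate the keys against the trait database
#'
#' Routes every species' centroid profile through the keys and reports, per
#' species, whether it identifies to itself, plus any boundary collisions: a
#' couplet on the species' traversal where moving a continuous trait across
#' its described range flips a lead, i.e. the described range straddles (or
#' touches) a key threshold, so real collections of the species can fall on
#' either side. Conflicts (couplets where no lead held) are reported, never
#' silently repaired.
#'
#' @param keys A `key_set`.
#' @param taxa A `taxon_db`.
#' @return An object of class `key_validation`: a list with `report` (one
#'   row per species: identified, correct, n_candidates, collision,
#'   conflict) and `collisions` (one row per species x couplet x field).
#' @export
validate_keys_against_taxa <- function(keys, taxa) {
  rows <- list(); colls <- list()
  for (t in taxa) {
    prof <- try(centroid_profile(t), silent = TRUE)
    if (inherits(prof, "try-error")) {
      rows[[t$name]] <- data.frame(
        species = t$name, identified = NA_character_, correct = FALSE,
        n_candidates = 0L, collision = NA, conflict = NA,
        stringsAsFactors = FALSE)
      next
    }
    id <- identify_specimen(prof, keys)
    has_coll <- FALSE
    for (vid in id$visited) {
      parts <- strsplit(vid, ":", fixed = TRUE)[[1]]
      leads <- keys$keys[[parts[1]]]$couplets[[parts[2]]]
      fields <- unique(unlist(lapply(leads, function(l)
        .collect_num_fields(l$predicate))))
      for (f in fields) {
        iv <- .field_interval(t, f)
        if (is.null(iv)) next
        # widen by a sampling-noise margin: the key sees the observed
        # collection mean, which scatters a few percent around the true
        # mean; counts (L) are read off exactly
        eps <- if (f == "lamellae_count") c(0, 0) else 0.03 * abs(iv)
        iv <- c(iv[1] - eps[1], iv[2] + eps[2])
        if (iv[1] == iv[2]) next
        flip <- vapply(iv, function(v) {
          p2 <- prof
          if (f == "stem_width") p2$qualitative$stem_width_range_cm <- c(v, v)
          else p2[[f]] <- v
          vals <- .couplet_lead_values(leads, p2)$values
          paste(vapply(vals, function(x) as.character(isTRUE(x)),
                       character(1)), collapse = "")
        }, character(1))
        if (flip[1] != flip[2]) {
          has_coll <- TRUE
          colls[[length(colls) + 1L]] <- data.frame(
            species = t$name, key = parts[1],
            couplet = as.integer(parts[2]), field = f,
            range_lo = iv[1], range_hi = iv[2], stringsAsFactors = FALSE)
        }
      }
    }
    rows[[t$name]] <- data.frame(
      species = t$name,
      identified = if (length(id$taxa) == 1L) id$taxa else
        paste(id$taxa, collapse = "|"),
      correct = length(id$taxa) == 1L && id$taxa == t$name,
      n_candidates = length(id$taxa),
      collision = has_coll,
      conflict = length(id$conflicts) > 0L,
      stringsAsFactors = FALSE)
  }
  out <- list(
    report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    collisions = if (length(colls))
      do.call(rbind, c(colls, list(make.row.names = FALSE))) else
      data.frame(species = character(), key = character(),
                 couplet = integer(), field = character(),
                 range_lo = numeric(), range_hi = numeric())
  )
  class(out) <- "key_validation"
  out
}

#' @export
print.key_validation <- function(x, ...) {
  ok <- sum(x$report$correct)
  cat(sprintf("Key validation: %d/%d species identify exactly from their centroid\n",
              ok, nrow(x$report)))
  bad <- x$report[!x$report$correct, , drop = FALSE]
  if (nrow(bad)) {
    cat("  not exact:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("    %-18s -> %s%s\n", bad$species[i], bad$identified[i],
                  if (isTRUE(bad$conflict[i])) " (couplet conflict)" else ""))
  }
  cat(sprintf("  boundary collisions: %d species, %d couplet x trait cases\n",
              length(unique(x$collisions$species)), nrow(x$collisions)))
  invisible(x)
}
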