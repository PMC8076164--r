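test_that("the packaged keys enumerate the right terminals", {
  expect_equal(length(key_terminals(gl_keys)), 28L)
  # the three species keys cover 27 species; the section key adds one more
  section_keys <- c("hebeloma", "denudata", "velutipes")
  inside <- unique(unlist(lapply(section_keys, key_terminals, keys = gl_keys)))
  expect_equal(length(inside), 27L)
  expect_equal(length(key_terminals(gl_keys, "hebeloma")), 14L)
  expect_equal(length(key_terminals(gl_keys, "denudata")), 10L)
  expect_equal(length(key_terminals(gl_keys, "velutipes")), 3L)
  expect_setequal(setdiff(key_terminals(gl_keys), inside), "islandicum")
})

test_that("structural defects in a key file are rejected at load", {
  raw <- jsonlite::fromJSON(hebeloma_file("greenland_keys.json"),
                            simplifyVector = FALSE)
  raw$keys$velutipes$couplets[["1"]][[2]]$outcome <- list(couplet = 99)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE)
  expect_error(load_keys(bad), "dangling couplet")
  # a cycle
  raw2 <- jsonlite::fromJSON(hebeloma_file("greenland_keys.json"),
                             simplifyVector = FALSE)
  raw2$keys$velutipes$couplets[["2"]][[2]]$outcome <- list(couplet = 1)
  cyc <- tempfile(fileext = ".json")
  jsonlite::write_json(raw2, cyc, auto_unbox = TRUE)
  expect_error(load_keys(cyc), "cycle|unreachable")
})

test_that("predicates evaluate with three-valued logic", {
  # a profile matching "Spores O2 to O3 and D2 to D3, many D3"
  prof <- specimen_profile(ornamentation = "O2O3", dextrinoidity = "D2D3")
  pred <- list(type = "and", args = list(
    list(type = "or", args = list(
      list(type = "ord", scale = "ornamentation", class = "O2", mode = "has"),
      list(type = "ord", scale = "ornamentation", class = "O3", mode = "has"))),
    list(type = "or", args = list(
      list(type = "ord", scale = "dextrinoidity", class = "D2", mode = "has"),
      list(type = "ord", scale = "dextrinoidity", class = "D3", mode = "has"))),
    list(type = "ord", scale = "dextrinoidity", class = "D3", mode = "many")))
  expect_true(evaluate_predicate(pred, prof))

  # "Spores, on ave. >= 6.7 um wide" against a 6.2 um profile
  narrow <- specimen_profile(mean_width = 6.2)
  expect_false(evaluate_predicate(
    list(type = "num", field = "mean_width", op = ">=", value = 6.7), narrow))

  # Kleene AND: unknown lamellae count with a true conjunct stays unknown
  half <- specimen_profile(qualitative = list(pileus_pubescent = TRUE))
  kleene <- list(type = "and", args = list(
    list(type = "num", field = "lamellae_count", op = "<", value = 32),
    list(type = "qual", field = "pileus_pubescent", value = TRUE)))
  expect_true(is.na(evaluate_predicate(kleene, half)))
  # ... but a false conjunct decides it
  bald <- specimen_profile(qualitative = list(pileus_pubescent = FALSE))
  expect_false(evaluate_predicate(kleene, bald))
  expect_error(evaluate_predicate(
    list(type = "num", field = "girth", op = "<", value = 1), half),
    "undefined")
})

test_that("characteristic specimens identify to the expected species", {
  # veil present, ellipsoid indextrinoid spores, L = 28, pubescent pileus
  pub <- specimen_profile(
    mean_length = 11, mean_width = 6.2, mean_q = 1.7, lamellae_count = 28,
    ornamentation = "O1O2", perispore = "P0", dextrinoidity = "D0",
    qualitative = list(veil_present = TRUE, pileus_pubescent = TRUE,
                       spore_shape_majority = "ellipsoid",
                       cheilocystidia_form = "ventricose_lageniform"))
  expect_equal(identify_specimen(pub, gl_keys)$taxa, "pubescens")

  # veil absent, hourglass cystidia, large strongly dextrinoid spores
  vac <- specimen_profile(
    mean_length = 13.0, mean_width = 7.2, mean_q = 1.8, lamellae_count = 46,
    ornamentation = "O3O4", perispore = "P1P2", dextrinoidity = "D2D3",
    qualitative = list(veil_present = FALSE, cheilocystidia_form = "hourglass",
                       spore_shape_majority = "amygdaloid",
                       cap_dark_reddish = TRUE, cap_center_pale = FALSE))
  expect_equal(identify_specimen(vac, gl_keys)$taxa, "vaccinum")

  # a fully unknown profile keeps all 28 species in play
  blank <- specimen_profile(habitat_arctic_alpine = NA)
  id <- identify_specimen(blank, gl_keys)
  expect_length(id$taxa, 28L)
})

test_that("identification paths are recorded for the deterministic part", {
  prof <- centroid_profile(gl_taxa$grandisporum)
  id <- identify_specimen(prof, gl_keys)
  expect_equal(id$taxa, "grandisporum")
  expect_gt(nrow(id$path), 0)
  expect_equal(id$path$key[1], "sections")
  expect_equal(id$path$couplet[1], 1L)
  expect_length(id$indeterminate_traits, 0)
})

test_that("refining an unknown trait never enlarges the candidate set", {
  fields_q <- c("veil_present", "pileus_pubescent", "cap_bicolored",
                "cheilocystidia_form", "spore_shape_majority", "papilla",
                "apical_wall_thickening", "cap_center_pale",
                "cap_dark_reddish", "cap_overhanging")
  set.seed(7)
  for (i in 1:30) {
    sp <- sample(names(gl_taxa), 1)
    full <- centroid_profile(gl_taxa[[sp]])
    partial <- full
    # blank a random subset of traits
    drop_num <- sample(c("mean_length", "mean_width", "lamellae_count"),
                       sample(0:2, 1))
    for (f in drop_num) partial[[f]] <- NULL
    drop_q <- sample(fields_q, sample(1:5, 1))
    for (f in drop_q) partial$qualitative[[f]] <- NULL
    if (runif(1) < 0.3) partial$dextrinoidity <- NULL
    coarse <- identify_specimen(partial, gl_keys)$taxa
    # restore one dropped trait
    refined <- partial
    back <- c(drop_num, drop_q)[1]
    if (back %in% fields_q) refined$qualitative[[back]] <-
        full$qualitative[[back]]
    else refined[[back]] <- full[[back]]
    finer <- identify_specimen(refined, gl_keys)$taxa
    expect_true(all(finer %in% coarse),
                info = sprintf("species %s, restored %s", sp, back))
  }
})

test_that("key/description cross-validation reports the known conflicts", {
  v <- validate_keys_against_taxa(gl_keys, gl_taxa)
  expect_equal(nrow(v$report), 28L)
  expect_equal(sum(v$report$correct), 26L)
  # the two documented conflicts: arcticum's O1 description vs the couplet
  # demanding O2-O3 (dead couplet, candidate set), and aurantioumbrinum's
  # 10-12 um range centred exactly on the 11 um threshold
  bad <- v$report[!v$report$correct, ]
  expect_setequal(bad$species, c("arcticum", "aurantioumbrinum"))
  expect_true(grepl("arcticum", bad$identified[bad$species == "arcticum"]))
  expect_true(v$report$conflict[v$report$species == "arcticum"])
  expect_true(v$report$collision[v$report$species == "aurantioumbrinum"])
  # the documented touch case: spetsbergense's 7.5 um lower bound sits on
  # the couplet-12 width threshold
  expect_true("spetsbergense" %in% v$collisions$species)
  sp12 <- v$collisions[v$collisions$species == "spetsbergense", ]
  expect_true(any(sp12$couplet == 12 & sp12$field == "mean_width"))
  # centroid identifications promised by the descriptions
  expect_true(v$report$correct[v$report$species == "grandisporum"])
  expect_true(v$report$correct[v$report$species == "colvinii"])
})

test_that("an impoverished taxon is reported unidentifiable, not fatal", {
  t <- gl_taxa$minus
  t$spore_mean_length_range <- NULL
  fake <- gl_taxa
  fake$minus <- t
  v <- validate_keys_against_taxa(gl_keys, fake)
  row <- v$report[v$report$species == "minus", ]
  expect_false(row$correct)
  expect_equal(row$n_candidates, 0L)
})
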