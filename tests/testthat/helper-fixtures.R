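# shared fixtures, loaded once per test run
gl_taxa <- load_taxa()
gl_keys <- load_keys()
gl_catalogue <- load_catalogue(species_whitelist = names(gl_taxa))

# collection counts per species as printed in the
# distribution-group table
gl_expected_counts <- c(
  alpinicola = 13, alpinum = 36, arcticum = 8, aurantioumbrinum = 40,
  clavulipes = 1, colvinii = 5, dunense = 42, excedens = 3, fuscatum = 8,
  geminatum = 3, grandisporum = 2, helodes = 5, hiemale = 44,
  hygrophilum = 15, ingratum = 4, islandicum = 1, leucosarx = 2,
  louiseae = 5, marginatulum = 42, mesophaeum = 11, minus = 2,
  nigellum = 21, oreophilum = 18, pubescens = 3, spetsbergense = 12,
  subconcolor = 9, vaccinum = 13, velutipes = 10)

# independent brute-force Hamming distance used as oracle in variant tests
brute_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- 0L
  for (k in seq_along(ca)) if (ca[k] != cb[k]) n <- n + 1L
  n
}
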