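# Shared fixtures: memoized full network and small programmatic test
# systems (toy networks and meshes built in code).

.fixEnv <- new.env(parent = emptyenv())

fullNet <- function() {
  if (is.null(.fixEnv$net)) .fixEnv$net <- loadNetwork()
  .fixEnv$net
}

# write a toy model (reaction table + species table) and load it
toyNetwork <- function(reactions, species) {
  rf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  sf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(reactions, rf)
  writeLines(c("name\tD\tcomposition", species), sf)
  loadNetwork(rf, sf)
}

# chain of n equal boxes coupled in series
chainMesh <- function(n, volume = 1, area = 1, dist = 1) {
  sv <- data.frame(id = seq_len(n) - 1L, region = "dend.cyt",
                   x = (seq_len(n) - 0.5) * dist, y = 0, z = 0,
                   volume = volume, spine = NA_integer_)
  cp <- if (n > 1) data.frame(a = 0:(n - 2), b = 1:(n - 1),
                              area = area, dist = dist)
  else data.frame(a = integer(0), b = integer(0),
                  area = numeric(0), dist = numeric(0))
  new("Mesh", subvolumes = sv, couplings = cp, spines = list(),
      meta = list(type = "chain", neckLength = NA, coarse = FALSE,
                  dx = dist, spineAxial = integer(0)))
}

initFromCounts <- function(mesh, network, counts) {
  m <- matrix(0, nrow(mesh@subvolumes), nrow(network@species),
              dimnames = list(NULL, network@species$name))
  for (s in names(counts)) m[, s] <- counts[[s]]
  new("InitialState", counts = m, stochastic = TRUE)
}

# moiety totals of a counts matrix
moietyTotals <- function(network, counts) {
  vapply(conservedMoieties(network, verify = FALSE),
         function(w) sum(counts %*% w), 0)
}
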