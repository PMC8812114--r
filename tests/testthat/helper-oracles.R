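# Independent brute-force oracles used to validate the fast implementations.

# Pinned isotope data, restated here independently of the package internals.
oracle_isotopes <- list(
  H  = data.frame(mass = c(1.0078250319, 2.0141017781), p = c(0.999885, 0.000115)),
  C  = data.frame(mass = c(12.0, 13.0033548351), p = c(0.9893, 0.0107)),
  N  = data.frame(mass = c(14.0030740044, 15.0001088989), p = c(0.99636, 0.00364)),
  O  = data.frame(mass = c(15.9949146196, 16.9991317565, 17.9991596129),
                  p = c(0.99757, 0.00038, 0.00205)),
  S  = data.frame(mass = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
                  p = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = data.frame(mass = c(34.9688526820, 36.9659026020), p = c(0.7576, 0.2424)),
  Br = data.frame(mass = c(78.9183376000, 80.9162897000), p = c(0.5069, 0.4931))
)

# Exhaustive isotopologue enumeration: every atom independently takes one of
# its element's isotopes; mass = sum, probability = product. Then merge
# within the resolution bin (abundance-weighted centroid, single linkage on
# the sorted masses), prune relative to the base peak, renormalize.
oracle_isotope_pattern <- function(counts, resolution_bin = 0.01, prune = 1e-4) {
  atoms <- rep(names(counts), unlist(counts))
  mass <- 0; prob <- 1
  for (el in atoms) {
    iso <- oracle_isotopes[[el]]
    mass <- rep(mass, each = nrow(iso)) + rep(iso$mass, times = length(mass))
    prob <- rep(prob, each = nrow(iso)) * rep(iso$p, times = length(prob))
  }
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  cl <- integer(length(mass)); cur <- 1L; cl[1] <- 1L
  for (i in seq_along(mass)[-1]) {
    if (mass[i] - mass[i - 1] > resolution_bin) cur <- cur + 1L
    cl[i] <- cur
  }
  mz <- rel <- numeric(cur)
  for (g in seq_len(cur)) {
    sel <- cl == g
    mz[g] <- sum(mass[sel] * prob[sel]) / sum(prob[sel])
    rel[g] <- sum(prob[sel])
  }
  rel <- rel / max(rel)
  keep <- rel > prune
  data.frame(mz = mz[keep], rel_intensity = rel[keep])
}

# Random small formula over {C,H,N,O,S,Cl,Br} with a bounded enumeration size.
random_small_formula <- function(max_atoms = 12, max_enum = 2e5) {
  repeat {
    els <- sample(names(oracle_isotopes), sample(1:4, 1))
    n_total <- sample(seq_len(max_atoms), 1)
    counts <- as.list(table(sample(els, n_total, replace = TRUE)))
    enum <- prod(vapply(names(counts),
                        function(e) nrow(oracle_isotopes[[e]])^counts[[e]],
                        numeric(1)))
    if (enum <= max_enum) return(counts)
  }
}
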