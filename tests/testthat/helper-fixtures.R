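# Shared fixtures: toy subunits/assemblies and a brute-force crosslink
# distance oracle that enumerates every chain pair naively.

toy_subunit <- function(identity = "A", n_atoms = 5, seed = 1,
                        spread = 15) {
  set.seed(seed)
  subunit_model(identity, data.frame(
    resno = seq_len(n_atoms), atom = "CA",
    x = runif(n_atoms, -spread, spread),
    y = runif(n_atoms, -spread, spread),
    z = runif(n_atoms, -spread, spread)))
}

random_toy_assembly <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  radius <- runif(1, 10, 60)
  n_atoms <- sample(3:20, 1)
  build_ring(toy_subunit("A", n_atoms, seed = seed * 2 + 1),
             toy_subunit("B", n_atoms, seed = seed * 2 + 2),
             ring_spec(n, radius, sample(c("A", "B"), 1)))
}

# independent oracle: loop over every ordered chain pair and compute the
# minimum CA-CA distance under the stated admissibility policy
brute_force_best_distance <- function(record, assembly) {
  is_self <- record$protein_a == record$protein_b &&
    record$residue_a == record$residue_b
  best <- Inf
  n <- assembly$spec$n
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ci <- assembly$chains[[i]]; cj <- assembly$chains[[j]]
      if (ci$identity != record$protein_a) next
      if (cj$identity != record$protein_b) next
      if (is_self && i == j) next
      ai <- ci$atoms[ci$atoms$atom == "CA" &
                       ci$atoms$resno == record$residue_a, ]
      aj <- cj$atoms[cj$atoms$atom == "CA" &
                       cj$atoms$resno == record$residue_b, ]
      if (nrow(ai) == 0 || nrow(aj) == 0) next
      d <- sqrt((ai$x - aj$x)^2 + (ai$y - aj$y)^2 + (ai$z - aj$z)^2)
      best <- min(best, d)
    }
  }
  best
}

# pair of bell assemblies differing only in identity pattern (6A/5B vs
# 5A/6B), built from identically shaped synthetic subunits
bell_assembly_pair <- function(seed = 1, n_residues = 40, radius = NULL) {
  geom <- bell_geometry()
  if (is.null(radius)) radius <- default_placement_radius(geom)
  sub_a <- synthetic_bell_subunit(geom, n_residues, seed = seed,
                                  identity = "A")
  sub_b <- synthetic_bell_subunit(geom, n_residues, seed = seed + 1000,
                                  identity = "B")
  list(a6b5 = build_ring(sub_a, sub_b, ring_spec(11, radius, "A")),
       a5b6 = build_ring(sub_a, sub_b, ring_spec(11, radius, "B")))
}

# small smooth random volume (band-limited white noise)
smooth_random_volume <- function(n = 48, voxel = 4, seed = 1, sigma_k = 5) {
  set.seed(seed)
  g <- array(rnorm(n^3), dim = c(n, n, n))
  k <- c(0:(n / 2), -((n / 2 - 1):1))
  kx <- array(rep(k, times = n * n), dim = dim(g))
  ky <- array(rep(rep(k, each = n), times = n), dim = dim(g))
  kz <- array(rep(k, each = n * n), dim = dim(g))
  lp <- exp(-(kx^2 + ky^2 + kz^2) / (2 * sigma_k^2))
  density_volume(Re(fft(fft(g) * lp, inverse = TRUE)) / n^3, voxel)
}
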