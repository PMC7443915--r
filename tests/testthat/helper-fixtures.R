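# Shared fixtures and independent oracles used across the suite.

# Two-fragment record with identity overlap: atom 1 (fragment A) owns basis
# functions 1:2, atom 2 (fragment B) owns 3:4. MO 1 lives on A, MO 2 on B.
tiny_two_fragment_record <- function(d_apart = 5, states = list()) {
  geom <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(d_apart, 0, 0)))
  S <- diag(4)
  C <- cbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  mos <- moset(C, n_occupied = 1, S = S)
  calculation_record(geom, basis_map = c(1, 1, 2, 2), overlap = S,
                     mos = mos, states = states)
}

tiny_two_fragment_map <- function() {
  fragment_map(list(A = 1L, B = 2L), n_atoms = 2)
}

# Brute-force Mulliken oracle: build the rank-1 density P = c c' explicitly,
# take diag(P S), and sum over the basis functions of each fragment.
oracle_fragment_profile <- function(C, S, basis_map, fmap, mo) {
  P <- tcrossprod(C[, mo])
  per_bf <- diag(P %*% S)
  frag_of_bf <- fragment_of_atom(fmap)[basis_map]
  lev <- fragment_names(fmap)
  100 * vapply(lev, function(f) sum(per_bf[frag_of_bf == f]), numeric(1))
}

# Brute-force difference-density oracle: assemble DeltaP explicitly from the
# normalized CI weights, Mulliken-partition diag(DeltaP S) onto atoms.
oracle_delta_populations <- function(state, record) {
  C <- record$mos$C; S <- record$overlap
  c2 <- state$transitions$amplitude^2
  w <- c2 / sum(c2)
  dP <- matrix(0, nrow(C), nrow(C))
  for (i in seq_along(w)) {
    a <- state$transitions$virt[i]; o <- state$transitions$occ[i]
    dP <- dP + w[i] * (tcrossprod(C[, a]) - tcrossprod(C[, o]))
  }
  per_bf <- diag(dP %*% S)
  vapply(seq_len(nrow(record$geometry)),
         function(at) sum(per_bf[record$basis_map == at]), numeric(1))
}

# Random S-normalized coefficient vector for a given SPD overlap
random_normalized_mo <- function(S) {
  v <- stats::rnorm(nrow(S))
  v / sqrt(sum(v * (S %*% v)))
}

# One-transition excited state helper
one_transition_state <- function(k = 1, energy = 2, f = 0.4, occ = 1, virt = 2,
                                 amplitude = 0.6) {
  excited_state(k, energy, f, data.frame(occ = occ, virt = virt,
                                         amplitude = amplitude))
}
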