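test_that("percentage contributions follow the restricted 200c^2 convention", {
  s1 <- one_transition_state(amplitude = 0.5)
  w1 <- transition_weights(s1)
  expect_equal(w1$percent, 50)
  expect_equal(w1$weight, 1)

  s2 <- excited_state(1, 2, 0.3, data.frame(occ = c(1, 1), virt = c(2, 3),
                                            amplitude = c(0.6, 0.2)))
  w2 <- transition_weights(s2)
  expect_equal(w2$percent, c(72, 8))
  expect_equal(w2$weight, c(0.9, 0.1))
  expect_equal(sum(w2$weight), 1, tolerance = 1e-9)

  s0 <- excited_state(1, 2, 0.3, data.frame(occ = 1, virt = 2, amplitude = 0))
  expect_error(transition_weights(s0), "all-zero")
})

test_that("state labels follow the weighted occupied-MO argmax", {
  # sole transition, occupied MO 95% on PheD2
  profs <- rbind(c(PD1 = 2, PheD2 = 95, ChlD1 = 3, environment = 0),
                 c(PD1 = 60, PheD2 = 10, ChlD1 = 30, environment = 0),
                 c(PD1 = 10, PheD2 = 10, ChlD1 = 80, environment = 0))
  s <- excited_state(1, 2, 0.3, data.frame(occ = 1, virt = 4, amplitude = 0.6))
  expect_equal(assign_state_label(s, profs), "PheD2")

  # two transitions, weights 0.7/0.3, occupied MOs on ChlD1 / PD1:
  # oracle = enumerate the weighted average over every fragment
  amp <- c(sqrt(0.35), sqrt(0.15))  # c^2 ratio 0.7 : 0.3
  s2 <- excited_state(1, 2, 0.3, data.frame(occ = c(3, 2), virt = c(4, 5),
                                            amplitude = amp))
  wavg <- 0.7 * profs[3, ] + 0.3 * profs[2, ]
  oracle <- names(which.max(wavg[setdiff(names(wavg), "environment")]))
  expect_equal(assign_state_label(s2, profs), "ChlD1")
  expect_equal(assign_state_label(s2, profs), oracle)

  # environment only wins when it beats every cofactor
  profs_env <- rbind(c(PD1 = 30, PheD2 = 20, ChlD1 = 10, environment = 40))
  expect_equal(assign_state_label(s, profs_env), "environment")
})

test_that("label recovery is exact on localized synthetic states", {
  n_states_total <- 0; n_correct <- 0
  for (seed in 1:20) {
    sc_name <- c("local-excitation", "ct-up-active", "within-P",
                 "ct-down-inactive", "mixed")[(seed %% 5) + 1]
    made <- make_record(scenario(sc_name, localization = 0.92, seed = seed))
    profs <- all_profiles(made$record, made$fmap)
    labels <- vapply(made$record$states, assign_state_label, character(1),
                     mo_profiles = profs)
    n_states_total <- n_states_total + length(labels)
    n_correct <- n_correct + sum(labels == made$sidecar$states$label)
  }
  expect_gte(n_states_total, 100)
  expect_equal(n_correct, n_states_total)
})

test_that("CT direction classification covers the branch scheme", {
  topo <- default_topology()
  lev <- c(CANONICAL_COFACTORS, "environment")
  prof_on <- function(frag, pct = 90) {
    p <- stats::setNames(rep((100 - pct) / (length(lev) - 1), length(lev)), lev)
    p[frag] <- pct
    p
  }
  cases <- list(
    list("ChlD1", "PheD1", "up-active"),
    list("PheD2", "PD2", "down-inactive"),
    list("PD1", "ChlD1", "up-active"),
    list("PD2", "PheD1", "up-active"),
    list("PD1", "ChlD2", "up-inactive"),
    list("PheD1", "PD1", "down-active"),
    list("ChlD2", "PD1", "down-inactive"),
    list("PD1", "PD2", "within-P"),
    list("ChlD1", "PheD2", "other"),
    list("ChlD1", "environment", "other"))
  for (cs in cases) {
    d <- transition_ct(prof_on(cs[[1]]), prof_on(cs[[2]]), topo)
    expect_equal(d$category, cs[[3]])
    expect_equal(d$donor, cs[[1]])
    expect_equal(d$acceptor, cs[[2]])
  }
  # identical profiles are local with zero magnitude
  d0 <- transition_ct(prof_on("PD1"), prof_on("PD1"), topo)
  expect_equal(d0$category, "local")
  expect_equal(d0$magnitude, 0)
  # sub-threshold transfer is local
  small <- prof_on("ChlD1", 90); small["PheD1"] <- small["PheD1"] + 3
  small["ChlD1"] <- small["ChlD1"] - 3
  expect_equal(transition_ct(prof_on("ChlD1", 90), small, topo)$category, "local")
})

test_that("swapping occupied and virtual profiles flips up and down", {
  topo <- default_topology()
  set.seed(99)
  flips <- c("up-active" = "down-active", "down-active" = "up-active",
             "up-inactive" = "down-inactive", "down-inactive" = "up-inactive",
             "within-P" = "within-P", "local" = "local")
  made_pairs <- list(c("PD1", "ChlD1"), c("ChlD1", "PheD1"), c("PheD2", "PD2"),
                     c("PD2", "ChlD2"), c("PD1", "PD2"), c("ChlD1", "ChlD1"))
  lev <- c(CANONICAL_COFACTORS, "environment")
  for (pair in made_pairs) {
    base <- stats::setNames(runif(length(lev), 0, 2), lev)
    occ <- base; occ[pair[1]] <- occ[pair[1]] + 90
    vir <- base; vir[pair[2]] <- vir[pair[2]] + 90
    occ <- 100 * occ / sum(occ); vir <- 100 * vir / sum(vir)
    fwd <- transition_ct(occ, vir, topo)
    rev <- transition_ct(vir, occ, topo)
    expect_equal(rev$category, unname(flips[fwd$category]))
    if (fwd$category != "local") {
      expect_equal(rev$donor, fwd$acceptor)
      expect_equal(rev$acceptor, fwd$donor)
    }
  }
})

test_that("planted CT categories are recovered across seeds", {
  for (seed in 1:12) {
    nm <- c("ct-up-active", "ct-down-active", "ct-up-inactive",
            "ct-down-inactive", "within-P", "local-excitation")[(seed %% 6) + 1]
    made <- make_record(scenario(nm, seed = 400 + seed))
    chars <- characterize_states(made$record, made$fmap)
    for (i in seq_along(chars)) {
      intended <- made$sidecar$states$category[i]
      expect_gte(chars[[i]]$ct_profile[[intended]],
                 if (intended == "local") 0.99 else 0.9)
      expect_equal(sum(chars[[i]]$ct_profile), 1, tolerance = 1e-9)
      expect_equal(sum(chars[[i]]$occ_profile), 100, tolerance = 1e-6)
    }
  }
})

test_that("a one-transition state's occupied profile equals its MO profile", {
  made <- make_record(scenario("ct-up-active", seed = 77))
  rec <- made$record
  s <- rec$states[[1]]
  tr <- s$transitions[1, , drop = FALSE]
  s1 <- excited_state(s$k, s$energy, s$f, tr)
  rec1 <- calculation_record(rec$geometry, rec$basis_map, rec$overlap, rec$mos,
                             list(s1), rec$meta)
  ch <- state_character(s1, rec1, made$fmap)
  profs <- all_profiles(rec, made$fmap)
  expect_equal(ch$occ_profile, profs[tr$occ, ], tolerance = 1e-12)
})

test_that("count_labels windows states by wavelength", {
  mk <- function(k, nm) one_transition_state(k = k, energy = EV_NM / nm)
  states <- list(mk(1, 420), mk(2, 430), mk(3, 410), mk(4, 500))
  labels <- c("PD1", "PD1", "PheD2", "PD1")
  counts <- count_labels(states, labels, c(396, 443))
  expect_equal(unname(counts["PD1"]), 2L)
  expect_equal(unname(counts["PheD2"]), 1L)
  expect_equal(sum(count_labels(states, labels, c(300, 350))), 0L)
  expect_error(count_labels(states, labels, c(400, 400)), "window")
})

test_that("soret scenario plants exactly six PD1 states in the Soret window", {
  for (seed in c(3, 17)) {
    made <- make_record(scenario("soret-pd1", seed = seed))
    expect_length(made$record$states, 22)
    profs <- all_profiles(made$record, made$fmap)
    labels <- vapply(made$record$states, assign_state_label, character(1),
                     mo_profiles = profs)
    counts <- count_labels(made$record$states, labels, c(396, 443))
    expect_equal(unname(counts["PD1"]), 6L)
    # eight of the ten Soret-window states are P chlorophyll excitations
    expect_equal(unname(counts["PD1"] + counts["PD2"]), 8L)
  }
})
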