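test_that("energy-wavelength conversion is an involution", {
  ev <- c(1.5, 1.9809, 2.5, 3.2, 0.01, 12)
  expect_equal(ev_to_nm(ev_to_nm(ev)), ev, tolerance = 1e-9)
  expect_equal(ev_to_nm(1), 1239.841984)
})

test_that("constructors enforce the record invariants", {
  expect_error(geometry("Xx", rbind(c(0, 0, 0))), "invalid element")
  expect_error(geometry("C", rbind(c(0, 0, Inf))), "finite")
  expect_error(validate_overlap(matrix(c(1, 0.2, 0.3, 1), 2)), "symmetric")
  expect_error(validate_overlap(diag(2) * 1.5), "diagonal")
  S_bad <- matrix(c(1, 0.999999999, 0.999999999, 1), 2)
  diag(S_bad) <- 1
  expect_error(moset(cbind(c(2, 0), c(0, 1)), 1, S = diag(2)), "S-normalized")
  expect_error(moset(diag(2), 2), "n_occupied")
  expect_error(excited_state(1, 2, -0.1,
                             data.frame(occ = 1, virt = 2, amplitude = 0.5)),
               "oscillator")
  expect_error(excited_state(1, 2, 0.1,
                             data.frame(occ = 2, virt = 1, amplitude = 0.5),
                             n_occupied = 1), "occ <= n_occupied < virt")
  st <- one_transition_state(energy = 2.1)
  expect_equal(st$wavelength, EV_NM / 2.1)
  # states must be sorted ascending in energy
  rec <- tiny_two_fragment_record()
  s1 <- one_transition_state(k = 1, energy = 2.2)
  s2 <- one_transition_state(k = 2, energy = 2.0)
  expect_error(calculation_record(rec$geometry, rec$basis_map, rec$overlap,
                                  rec$mos, list(s1, s2)), "sorted")
})

test_that("FCHK subset round-trips and derives the basis map from shells", {
  made <- make_record(scenario("local-excitation", n_fragments = 3, seed = 11))
  path <- withr::local_tempfile(fileext = ".fchk")
  write_fchk_subset(made$record, path)
  back <- read_fchk_subset(path)
  expect_equal(back$basis_map, made$record$basis_map)
  expect_equal(back$mos$C, made$record$mos$C, tolerance = 1e-7)
  expect_equal(back$overlap, made$record$overlap, tolerance = 1e-7)
  expect_equal(coords_angstrom <- as.matrix(back$geometry[, c("x", "y", "z")]),
               as.matrix(made$record$geometry[, c("x", "y", "z")]),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$mos$n_occupied, made$record$mos$n_occupied)
})

test_that("hand-written FCHK with 2 atoms and 4 s-shells maps owners (1,1,2,2)", {
  lines <- c(
    "tiny fixture",
    "SP        test                 test",
    sprintf("%-43s%s%17d", "Number of atoms", "I", 2L),
    sprintf("%-43s%s%17d", "Number of alpha electrons", "I", 1L),
    sprintf("%-43s%s   N=%12d", "Atomic numbers", "I", 2L),
    sprintf("%12d%12d", 1L, 6L),
    sprintf("%-43s%s   N=%12d", "Current cartesian coordinates", "R", 6L),
    paste0(sprintf("%16.8E", c(0, 0, 0, 1.88972613, 0, 0)), collapse = ""),
    sprintf("%-43s%s   N=%12d", "Shell types", "I", 4L),
    sprintf("%12d%12d%12d%12d", 0L, 0L, 0L, 0L),
    sprintf("%-43s%s   N=%12d", "Shell to atom map", "I", 4L),
    sprintf("%12d%12d%12d%12d", 1L, 1L, 2L, 2L),
    sprintf("%-43s%s   N=%12d", "Alpha MO coefficients", "R", 8L),
    paste0(sprintf("%16.8E", c(1, 0, 0, 0, 0)), collapse = ""),
    paste0(sprintf("%16.8E", c(0, 1, 0)), collapse = ""))
  path <- withr::local_tempfile(fileext = ".fchk")
  writeLines(lines, path)
  rec <- read_fchk_subset(path)
  expect_length(rec$basis_map, 4)
  expect_equal(rec$basis_map, c(1L, 1L, 2L, 2L))
  expect_equal(rec$geometry$element, c("H", "C"))
  expect_equal(rec$geometry$x[2], 1.88972613 * 0.52917721067, tolerance = 1e-7)
  expect_null(rec$overlap)
  # and the Mulliken stage refuses to run without an overlap
  fmap <- tiny_two_fragment_map()
  expect_error(fragment_profile(rec, fmap, 1), "overlap")
})

test_that("FCHK parser names the offending key on malformed input", {
  path <- withr::local_tempfile(fileext = ".fchk")
  writeLines(c("x", "y", sprintf("%-43s%s   N=%12d", "Atomic numbers", "I", 5L),
               "1 6"), path)
  expect_error(read_fchk_subset(path), "Atomic numbers")
  made <- make_record(scenario("local-excitation", n_fragments = 2, seed = 1))
  write_fchk_subset(made$record, path)
  txt <- readLines(path)
  txt <- sub("^Shell types.*", sprintf("%-43s%s   N=%12d", "Shell types", "I", 1L), txt)
  # now inject an unsupported shell code
  i <- grep("^Shell types", txt)
  txt[i + 1] <- sprintf("%12d", 9L)
  txt <- txt[-seq(i + 2, i + length(made$record$basis_map) %/% 6)]
  writeLines(txt, path)
  expect_error(read_fchk_subset(path), "Shell")
})

test_that("excitation log round-trips states, signs and f = 0", {
  tr1 <- data.frame(occ = c(3, 2), virt = c(9, 8),
                    amplitude = c(0.570200, -0.120000),
                    deexcitation = c(0, -0.031000))
  tr2 <- data.frame(occ = 1, virt = 7, amplitude = -0.650000, deexcitation = 0)
  states <- list(excited_state(1, 1.9809, 0.3120, tr1),
                 excited_state(2, 2.4100, 0.0000, tr2),
                 excited_state(3, 3.0000, 0.1200, tr2))
  path <- withr::local_tempfile(fileext = ".log")
  write_excitations_log(states, path)
  back <- read_excitations_log(path)
  expect_length(back, 3)
  expect_identical(back[[1]]$transitions$amplitude, tr1$amplitude)
  expect_identical(back[[1]]$transitions$deexcitation, tr1$deexcitation)
  expect_identical(back[[2]]$f, 0)
  expect_equal(back[[2]]$transitions$amplitude, -0.65)
  # no transition silently dropped: counts match what was written
  n_written <- sum(grepl("->", readLines(path)))
  expect_equal(sum(vapply(back, function(s) nrow(s$transitions), numeric(1))),
               n_written)
})

test_that("excitation log errors are descriptive", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(c("nothing", "to see"), path)
  expect_error(read_excitations_log(path), "no 'Excited State' block")
  writeLines(c(" Excited State   1:      Singlet-A    2.0000 eV   619.92 nm  f=0.1000",
               "    1 -> 2     zero.point.five"), path)
  expect_error(read_excitations_log(path), "line")
})

test_that("record container round-trips bit-exactly and enforces invariants", {
  set.seed(42)
  for (rep in 1:25) {
    nf <- sample(2:4, 1)
    made <- make_record(scenario("local-excitation", n_fragments = nf,
                                 atoms_per_fragment = sample(1:2, 1),
                                 bf_per_atom = sample(2:3, 1),
                                 n_states = sample(2:4, 1),
                                 seed = 1000 + rep))
    path <- withr::local_tempfile(fileext = ".json")
    write_record(made$record, path)
    back <- read_record(path)
    expect_identical(back$mos$C, made$record$mos$C)
    expect_identical(back$overlap, made$record$overlap)
    expect_identical(back$basis_map, made$record$basis_map)
    for (k in seq_along(back$states)) {
      expect_identical(back$states[[k]]$transitions$amplitude,
                       made$record$states[[k]]$transitions$amplitude)
      expect_identical(back$states[[k]]$energy, made$record$states[[k]]$energy)
    }
  }
  # a state with no transitions is rejected before writing
  rec <- tiny_two_fragment_record()
  expect_error(excited_state(1, 2, 0.1, data.frame(occ = integer(0),
                                                   virt = integer(0),
                                                   amplitude = numeric(0))),
               "non-empty")
})

test_that("Mulliken profiles survive a container round trip to 1e-12", {
  made <- make_record(scenario("ct-up-active", seed = 5))  # 6 fragments, 60 bf
  expect_length(made$record$basis_map, 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_record(made$record, path)
  back <- read_record(path)
  p1 <- all_profiles(made$record, made$fmap)
  p2 <- all_profiles(back, made$fmap)
  expect_equal(p1, p2, tolerance = 1e-12)
})
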