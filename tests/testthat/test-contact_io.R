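test_that("contact_data validates counts, symmetry and abundances", {
  cd <- toy_contacts()
  expect_s3_class(cd, "contact_data")
  expect_equal(cd$wins["A", "B"], 3)
  expect_equal(cd$draws["B", "A"], 2)

  w <- matrix(0, 2, 2); d <- matrix(0, 2, 2)
  expect_error(contact_data(c("A", "B"), -w - 1, d, c(1, 1)), "negative")
  d2 <- d; d2[1, 2] <- 3   # asymmetric draws
  expect_error(contact_data(c("A", "B"), w, d2, c(1, 1)), "asymmetric")
  expect_error(contact_data(c("A", "B"), w, d, c(0, 1)), "abundance")
})

test_that("long-format reading matches direct transcription", {
  dir <- withr::local_tempdir()
  writeLines(c("species_a\tspecies_b\twins_a\twins_b\tdraws",
               "A\tB\t3\t1\t2",
               "A\tC\t0\t0\t0",
               "B\tC\t5\t0\t1"),
             file.path(dir, "contests.tsv"))
  writeLines(c("species\tcolonies", "A\t8", "B\t5", "C\t12"),
             file.path(dir, "abund.tsv"))
  cd <- read_contacts(file.path(dir, "contests.tsv"), file.path(dir, "abund.tsv"))
  expect_equal(cd$species, c("A", "B", "C"))
  expect_equal(cd$wins["A", "B"], 3)
  expect_equal(cd$draws["B", "C"], 1)
  expect_equal(cd$draws["C", "B"], 1)   # symmetrised from the single record
  n <- cd$wins + t(cd$wins) + cd$draws
  expect_equal(n["A", "C"], 0)
})

test_that("empty contests file yields all-zero counts for listed species", {
  dir <- withr::local_tempdir()
  writeLines("species_a\tspecies_b\twins_a\twins_b\tdraws",
             file.path(dir, "contests.tsv"))
  writeLines(c("species\tcolonies", "A\t3", "B\t7"),
             file.path(dir, "abund.tsv"))
  cd <- read_contacts(file.path(dir, "contests.tsv"), file.path(dir, "abund.tsv"))
  expect_equal(length(cd$species), 2)
  expect_true(all(cd$wins == 0) && all(cd$draws == 0))
})

test_that("write/read round-trip is the identity", {
  dir <- withr::local_tempdir()
  cd <- toy_contacts()
  write_contacts(cd, file.path(dir, "c.tsv"), file.path(dir, "a.tsv"))
  back <- read_contacts(file.path(dir, "c.tsv"), file.path(dir, "a.tsv"),
                        assemblage_id = "toy")
  expect_equal(back$species, cd$species)
  expect_equal(back$wins, cd$wins)
  expect_equal(back$draws, cd$draws)
  expect_equal(back$abundance, cd$abundance)
})

test_that("wide dialect reads matrices and symmetrises one-sided draws", {
  dir <- withr::local_tempdir()
  sp <- c("A", "B")
  w <- matrix(c(0, 1, 4, 0), 2, 2, dimnames = list(sp, sp))
  d <- matrix(c(0, 0, 2, 0), 2, 2, dimnames = list(sp, sp))  # one-sided record
  write.csv(as.data.frame(w), file.path(dir, "wins.csv"))
  write.csv(as.data.frame(d), file.path(dir, "draws.csv"))
  writeLines(c("species\tcolonies", "A\t4", "B\t6"), file.path(dir, "abund.tsv"))
  cd <- read_contacts(file.path(dir, "wins.csv"), file.path(dir, "abund.tsv"),
                      draws_path = file.path(dir, "draws.csv"))
  expect_equal(cd$wins["A", "B"], 4)
  expect_equal(cd$draws["B", "A"], 2)
})

test_that("connectance counts interacting pairs and ignores species order", {
  cd <- toy_contacts()
  expect_equal(connectance(cd), 1.0)

  # remove the A-C contests -> 2 of 3 pairs
  w <- cd$wins; w["A", "C"] <- w["C", "A"] <- 0
  cd2 <- contact_data(cd$species, w, cd$draws, cd$abundance)
  expect_equal(connectance(cd2), 2 / 3)

  perm <- c(3, 1, 2)
  cd3 <- contact_data(cd$species[perm], cd$wins[perm, perm],
                      cd$draws[perm, perm], cd$abundance[perm])
  expect_equal(connectance(cd3), connectance(cd))

  empty <- contact_data(letters[1:5], matrix(0, 5, 5), matrix(0, 5, 5),
                        rep(1, 5))
  expect_equal(connectance(empty), 0)
})

test_that("win_loss_summary reports interacting pairs, intraspecific apart", {
  cd <- toy_contacts()
  tab <- win_loss_summary(cd)
  ab <- tab[tab$species_a == "A" & tab$species_b == "B", ]
  expect_equal(unlist(ab[, c("wins_a", "wins_b", "draws", "total")],
                      use.names = FALSE), c(3, 1, 2, 6))
  expect_true(all(tab$total == tab$wins_a + tab$wins_b + tab$draws))
  expect_false(any(tab$species_a == tab$species_b))

  intra <- intraspecific_summary(cd)
  expect_equal(intra$overgrowths[intra$species == "A"], 2)
  expect_equal(intra$ties[intra$species == "A"], 1)

  # non-interacting pair excluded
  w <- cd$wins; w["A", "C"] <- w["C", "A"] <- 0
  cd2 <- contact_data(cd$species, w, cd$draws, cd$abundance)
  tab2 <- win_loss_summary(cd2)
  expect_false(any(tab2$species_a == "A" & tab2$species_b == "C"))
})
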