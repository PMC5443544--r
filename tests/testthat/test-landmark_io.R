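test_that("TPS records are transcribed directly, with contract errors", {
  tmp <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=a"), tmp)
  d <- read_tps(tmp)
  expect_equal(length(d), 1L)
  expect_equal(d$k, 3L)
  expect_equal(unname(d$coords[, , 1]), rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_identical(d$specimen_id, "a")

  writeLines(c("LM=8", "0 0", "1 0", "0 1", "1 1", "2 0", "0 2", "2 2",
               "ID=bad"), tmp)
  expect_error(read_tps(tmp), "LM=8 but 7 coordinate lines")

  writeLines(c("LM=3", "0 0", "1 zebra", "0 1", "ID=a"), tmp)
  expect_error(read_tps(tmp), "coordinate line 2")
})

test_that("SCALE= is applied or ignored per policy and unknown keys warn", {
  tmp <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "2 0", "0 2", "ID=a", "SCALE=0.5",
               "CURVES=0"), tmp)
  expect_warning(d_apply <- read_tps(tmp, scale_policy = "apply"),
                 "unknown TPS key")
  expect_equal(unname(d_apply$coords[2, 1, 1]), 1)
  suppressWarnings(d_ignore <- read_tps(tmp, scale_policy = "ignore"))
  expect_equal(unname(d_ignore$coords[2, 1, 1]), 2)
  expect_equal(d_ignore$scale_factor, 0.5)
})

test_that("TPS write/read round trip is lossless to 1e-12", {
  set.seed(42)
  configs <- replicate(20, random_config(8), simplify = FALSE)
  d <- landmark_dataset(configs, sprintf("s%02d", 1:20),
                        rep(sprintf("sp%d", 1:5), each = 4), "dorsal",
                        scale_factor = runif(20, 0.5, 2))
  tmp <- withr::local_tempfile(fileext = ".tps")
  write_tps(d, tmp)
  d2 <- read_tps(tmp, scale_policy = "ignore", side = "dorsal",
                 species = d$species_id)
  expect_lt(max(abs(d2$coords - d$coords)), 1e-12)
  expect_identical(d2$specimen_id, d$specimen_id)
  expect_equal(d2$scale_factor, d$scale_factor, tolerance = 1e-12)
})

test_that("wide and long tabular layouts yield identical datasets", {
  set.seed(7)
  configs <- replicate(2, random_config(8), simplify = FALSE)
  d <- landmark_dataset(configs, c("s1", "s2"), c("spA", "spB"), "ventral")
  wide_path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(d, wide_path)
  d_wide <- read_landmark_table(wide_path, format = "csv")
  expect_equal(length(d_wide), 2L)
  expect_equal(d_wide$coords, d$coords, tolerance = 1e-12,
               ignore_attr = TRUE)

  long <- do.call(rbind, lapply(1:2, function(i)
    data.frame(specimen = d$specimen_id[i], species = d$species_id[i],
               side = "ventral", landmark = 1:8,
               x = d$coords[, 1, i], y = d$coords[, 2, i])))
  long_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, long_path, row.names = FALSE)
  d_long <- read_landmark_table(long_path, format = "csv")
  expect_equal(d_long$coords, d_wide$coords, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(d_long$species_id, d_wide$species_id)

  expect_error(read_landmark_table(long_path, format = "csv",
                                   column_map = list(specimen = "nope")),
               "not found")
})

test_that("dataset validation enforces the documented invariants", {
  cfg <- random_config(8)
  expect_error(landmark_dataset(list(matrix(0:5, 3, 2) * NA_real_),
                                "a", "sp", "ventral"), "finite")
  expect_error(landmark_dataset(list(cfg[1:2, ]), "a", "sp", "ventral"),
               "fewer than 3 landmarks")
  expect_error(landmark_dataset(list(cfg, cfg), c("a", "a"), c("s", "s"),
                                "ventral"), "duplicate specimen/side")
  # same specimen id on different sides is fine
  expect_silent(landmark_dataset(list(cfg, cfg), c("a", "a"), c("s", "s"),
                                 c("ventral", "dorsal")))
})

test_that("Newick reading validates and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tmp)
  tr <- read_phylogeny(tmp)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))

  writeLines("((A,B),C);", tmp)
  tr2 <- read_phylogeny(tmp)
  expect_null(tr2$edge.length)

  out <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, out)
  tr3 <- read_phylogeny(out)
  expect_true(isTRUE(all.equal(tr, tr3)))
  expect_equal(sum(tr3$edge.length), sum(tr$edge.length))

  writeLines("((A:1,A:1):1,C:2);", tmp)
  expect_error(read_phylogeny(tmp), "duplicate tip")
})

test_that("species/tip matching reports mismatches and honours aliases", {
  d <- landmark_dataset(replicate(3, random_config(), simplify = FALSE),
                        c("s1", "s2", "s3"),
                        c("Lcepha", "Lchaba", "Lmystery"), "ventral")
  tr <- ape::read.tree(text = "((Lcepha:1,Lchaba:1):1,Lconfu:2);")
  expect_warning(m <- match_species_tree(d, tr), "Lmystery")
  expect_equal(m$unmatched_species, "Lmystery")
  expect_equal(m$unused_tips, "Lconfu")
  m2 <- suppressWarnings(
    match_species_tree(d, tr, alias = c(Lmystery = "Lconfu")))
  expect_equal(length(m2$unmatched_species), 0L)
})
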