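test_that("TNT xread parsing handles the dialect", {
  tf <- withr::local_tempfile(lines = "xread 3 4 A 010 B 011 C 110 D 1?0 ;")
  m <- read_tnt_matrix(tf)
  expect_s3_class(m, "character_matrix")
  expect_equal(m$taxa, c("A", "B", "C", "D"))
  expect_equal(m$n_char, 3L)
  # '?' expands to full ambiguity for a 2-state character
  expect_equal(cell_states(m, "D", 2), c(0L, 1L))
  expect_equal(cell_states(m, "A", 1), 0L)

  tf2 <- withr::local_tempfile(lines = c("'a title comment'", "xread 2 4",
                                         "A 0[01]", "B 11", "C {12}0", "D 20", ";"))
  m2 <- read_tnt_matrix(tf2)
  expect_equal(cell_states(m2, "A", 2), c(0L, 1L))   # [..] brackets
  expect_equal(cell_states(m2, "C", 1), c(1L, 2L))   # {..} brackets
  expect_equal(m2$state_count, c(3L, 2L))

  # interleaved blocks concatenate
  tf3 <- withr::local_tempfile(lines = c("xread 4 2", "A 01", "B 10",
                                         "A 11", "B 00", ";"))
  m3 <- read_tnt_matrix(tf3)
  expect_equal(m3$n_char, 4L)
  expect_equal(vapply(1:4, function(j) cell_states(m3, "A", j), 1L), c(0L, 1L, 1L, 1L))
})

test_that("TNT parse errors are informative", {
  tf <- withr::local_tempfile(lines = "xread 3 4 A 010 B 01 C 110 D 100 ;")
  expect_error(read_tnt_matrix(tf), "ragged")
  tf2 <- withr::local_tempfile(lines = "no block here")
  expect_error(read_tnt_matrix(tf2), "xread")
  tf3 <- withr::local_tempfile(lines = "xread 2 2 A 0* B 00 ;")
  expect_error(read_tnt_matrix(tf3), "state symbol")
  expect_error(read_tnt_matrix(file.path(tempdir(), "nope.tnt")), "not found")
})

test_that("matrix round trip is cell-identical", {
  set.seed(4)
  m <- random_matrix(6, 12, k = 4L, seed = 4)
  # sprinkle ambiguity
  m$mask[2, 3] <- 3L
  m$mask[4, 7] <- bitwShiftL(1L, m$state_count[7]) - 1L
  tf <- withr::local_tempfile()
  write_tnt_matrix(m, tf)
  m2 <- read_tnt_matrix(tf)
  expect_identical(unname(m2$mask), unname(m$mask))
  expect_identical(m2$state_count, m$state_count)
  # idempotence: a second round trip changes nothing
  tf2 <- withr::local_tempfile()
  write_tnt_matrix(m2, tf2)
  expect_identical(unname(read_tnt_matrix(tf2)$mask), unname(m2$mask))
})

test_that("newick round trips preserve topology, lengths and ages", {
  t1 <- ape::read.tree(text = "((A,B),C);")
  expect_equal(ape::write.tree(ape::read.tree(text = write_newick(t1, FALSE))),
               "((A,B),C);")
  t1$tip.label[2] <- ""
  expect_error(write_newick(t1), "labelled")

  # sampled ancestor: zero-length terminal attachment survives the trip
  dt <- dated_tree(parent = c(3L, 3L, 0L), age = c(10, 4, 10),
                   labels = c("X", "Y"), sa = c(TRUE, FALSE), origin = 25)
  nwk <- write_newick(dated_to_phylo(dt))
  back <- read_newick(nwk, tip_ages = c(X = 10, Y = 4))
  expect_true(attr(back, "sampled_ancestor")[match("X", back$tip.label)])
  expect_false(attr(back, "sampled_ancestor")[match("Y", back$tip.label)])

  # node ages recovered within 1e-9 for a simulated tree
  cfg <- sim_config(seed = 8, min_samples = 5, max_samples = 10)
  sim <- simulate_fbd_tree(cfg)
  phy <- dated_to_phylo(sim)
  ages <- stats::setNames(sim$age[seq_len(sim$n_tip)], sim$labels)
  back2 <- read_newick(write_newick(phy), tip_ages = ages)
  a1 <- sort(attr(phy, "node_ages"))
  a2 <- sort(attr(back2, "node_ages"))
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("tip age table validation", {
  tf <- withr::local_tempfile(lines = c("taxon\tmean\tmin\tmax", "A\t80\t75\t85", "B\t92\t92\t92"))
  d <- read_tip_ages(tf)
  expect_equal(d$mean, c(80, 92))
  tf2 <- withr::local_tempfile(lines = c("taxon\tmean\tmin\tmax", "A\t80\t85\t85"))
  expect_error(read_tip_ages(tf2), "min <= mean <= max")
  tf3 <- withr::local_tempfile(lines = c("taxon\tmean", "A\t-4"))
  expect_error(read_tip_ages(tf3), "positive")
})

test_that("packaged registry loads 13 definitions with the stated structure", {
  path <- system.file("extdata", "table1_definitions.json", package = "mosaweak")
  defs <- read_definitions(path)
  expect_length(defs, 13L)
  nm <- vapply(defs, `[[`, "", "name")
  expect_equal(nm[1], "Mosasauroidea")
  expect_equal(nm[13], "Tylosaurinae")
  md <- defs[[match("Mosasauridae", nm)]]
  expect_equal(md$kind, "node")
  expect_length(md$internal, 3L)
  expect_length(md$external, 0L)
  ai <- defs[[match("Aigialosauridae", nm)]]
  expect_equal(ai$kind, "branch")
  expect_equal(sum(vapply(ai$external, inherits, TRUE, "node_of")), 1L)
  # schema errors
  bad <- withr::local_tempfile(lines = '[{"name": "X", "type": "ring", "internal": ["a","b"]}]')
  expect_error(read_definitions(bad))
  bad2 <- withr::local_tempfile(lines = '[{"name": "X", "type": "node", "internal": []}]')
  expect_error(read_definitions(bad2), "non-empty")
})

test_that("packaged ordered-character list has exactly the 19 indices", {
  idx <- read_character_indices(system.file("extdata", "ordered_characters.txt",
                                            package = "mosaweak"))
  expect_length(idx, 19L)
  expect_equal(idx, sort(c(1, 8, 10, 18, 20, 29, 30, 32, 37, 41, 53, 54, 55,
                           63, 72, 88, 96, 102, 110)))
})
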