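test_that("node- and branch-based evaluation on toy trees", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  dn <- phylo_definition("N", "node", internal = list("A", "B"), external = list("C"))
  oc <- evaluate_definition(dn, tr)
  expect_equal(oc$status, "APPLIES")
  expect_equal(oc$clade, c("A", "B"))
  tr2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(evaluate_definition(dn, tr2)$status, "SELF_DESTRUCTS")

  db <- phylo_definition("B", "branch", internal = list("A"), external = list("C"))
  expect_equal(evaluate_definition(db, tr)$clade, c("A", "B"))
  tr3 <- ape::read.tree(text = "((A,C),B);")
  expect_equal(evaluate_definition(db, tr3)$clade, "A")   # walk stops at once

  # unresolved internal specifier: NOT_EVALUABLE, never a guess
  dm <- phylo_definition("M", "node", internal = list("A", "Zz zz"), external = list())
  oc2 <- evaluate_definition(dm, tr)
  expect_equal(oc2$status, "NOT_EVALUABLE")
  expect_match(oc2$reason, "Zz zz")
})

test_that("specifier resolution: verbatim, proxy map, genus fallback", {
  tr <- ape::read.tree(text = "((Plioplatecarpus_sp,Platecarpus_tympaniticus),(Mosasaurus_hoffmannii,Globidens_alabamaensis));")
  tr$tip.label <- gsub("_", " ", tr$tip.label)
  d <- phylo_definition("X", "node",
                        internal = list("Mosasaurus hoffmannii", "Plioplatecarpus marshii"))
  rs <- resolve_specifiers(d, tr)
  expect_equal(unname(unlist(rs$internal)),
               c("Mosasaurus hoffmannii", "Plioplatecarpus sp"))   # genus fallback
  expect_length(rs$unresolved, 0L)
  # explicit proxy beats fallback; NONE forces unresolved
  pm <- c("Plioplatecarpus marshii" = "Platecarpus tympaniticus")
  rs2 <- resolve_specifiers(d, tr, pm)
  expect_equal(unname(rs2$internal[[2]]), "Platecarpus tympaniticus")
  rs3 <- resolve_specifiers(d, tr, c("Plioplatecarpus marshii" = "NONE"))
  expect_equal(rs3$unresolved, "Plioplatecarpus marshii")
  # ambiguous genus fallback (two congeners) stays unresolved
  tr2 <- ape::read.tree(text = "((Globidens alabamaensis X,Globidens dakotensis X),(A,B));")
  tr2$tip.label <- c("Globidens alabamaensis", "Globidens dakotensis", "A", "B")
  d2 <- phylo_definition("Y", "node", internal = list("A", "Globidens schurmanni"))
  expect_equal(evaluate_definition(d2, tr2)$status, "NOT_EVALUABLE")
})

test_that("composite (clade-valued) external specifiers", {
  # Aigialosauridae-style: self-destructs when the internals sit inside the
  # composite external clade
  d <- phylo_definition("AigStyle", "branch",
                        internal = list("a1", "a2"),
                        external = list("out", node_of(c("m1", "m2", "m3"))))
  t_ok <- ape::read.tree(text = "(out,((a1,a2),(m1,(m2,m3))));")
  oc <- evaluate_definition(d, t_ok)
  expect_equal(oc$status, "APPLIES")
  expect_equal(oc$clade, c("a1", "a2"))
  t_in <- ape::read.tree(text = "(out,((m1,(a1,a2)),(m2,m3)));")
  expect_equal(evaluate_definition(d, t_in)$status, "SELF_DESTRUCTS")
})

test_that("evaluator matches exhaustive predicate enumeration on all 6-leaf rooted trees", {
  # all rooted 6-leaf topologies = all unrooted 7-leaf topologies rooted on
  # the extra leaf (945 trees)
  taxa <- c("ROOT", "A", "B", "C", "D", "E", "F")
  all7 <- all_unrooted_topologies(taxa)
  expect_length(all7, 945L)
  defs <- list(
    phylo_definition("br", "branch", internal = list("A"), external = list("C", "E")),
    phylo_definition("cmp", "branch", internal = list("A", "B"),
                     external = list(node_of(c("D", "E", "F"))))
  )
  # branch-based semantics: the definition applies iff some clade satisfies
  # the predicate, and then names the largest such clade
  for (i in seq_along(all7)) {
    r6 <- ape::drop.tip(root_on_taxon(all7[[i]], "ROOT"), "ROOT")
    for (d in defs) {
      oc <- evaluate_definition(d, r6)
      sats <- satisfying_clades(d, r6)
      if (length(sats) == 0) {
        expect_equal(oc$status, "SELF_DESTRUCTS", info = paste("tree", i, d$name))
      } else {
        biggest <- sats[[which.max(vapply(sats, length, 1L))]]
        expect_equal(oc$status, "APPLIES", info = paste("tree", i, d$name))
        expect_identical(sort(oc$clade), sort(biggest), info = paste("tree", i, d$name))
      }
    }
  }
})

test_that("node-based status equals direct MRCA predicate on all rooted trees", {
  taxa <- c("ROOT", "A", "B", "C", "D", "E", "F")
  all7 <- all_unrooted_topologies(taxa)
  d <- phylo_definition("nd", "node", internal = list("A", "B"), external = list("C", "F"))
  for (i in seq_along(all7)) {
    r6 <- ape::drop.tip(root_on_taxon(all7[[i]], "ROOT"), "ROOT")
    oc <- evaluate_definition(d, r6)
    # direct oracle: MRCA leaf set by brute force over node leaf sets
    sets <- mosaweak:::node_leafsets(r6)
    cand <- Filter(function(s) all(c("A", "B") %in% s), sets)
    mrca <- cand[[which.min(vapply(cand, length, 1L))]]
    intruded <- any(c("C", "F") %in% mrca)
    expect_equal(oc$status == "SELF_DESTRUCTS", intruded, info = paste("tree", i))
    if (!intruded) expect_identical(sort(oc$clade), sort(mrca))
  }
})

test_that("branch-based contains node-based; rotation invariance; polytomy MRCA", {
  set.seed(101)
  for (i in 1:10) {
    tr <- ape::rtree(7, tip.label = paste0("t", 1:7)); tr$edge.length <- NULL
    dn <- phylo_definition("n", "node", internal = list("t1", "t2"), external = list("t3"))
    db <- phylo_definition("b", "branch", internal = list("t1", "t2"), external = list("t3"))
    on <- evaluate_definition(dn, tr); ob <- evaluate_definition(db, tr)
    expect_equal(on$status, ob$status)
    if (on$status == "APPLIES") expect_true(all(on$clade %in% ob$clade))
    rot <- ape::rotateConstr(tr, rev(tr$tip.label))
    expect_equal(evaluate_definition(dn, rot)$status, on$status)
  }
  # hard polytomy: MRCA at the polytomy includes all its children
  pt <- ape::read.tree(text = "((A,B,C),(D,E));")
  d <- phylo_definition("p", "node", internal = list("A", "B"), external = list("D"))
  oc <- evaluate_definition(d, pt)
  expect_equal(sort(oc$clade), c("A", "B", "C"))
})

test_that("weak-spot report statuses, fractions and summary classes", {
  t_ab <- ape::read.tree(text = "(((A,B),C),D);")
  t_ac <- ape::read.tree(text = "(((A,C),B),D);")
  defs <- list(
    phylo_definition("AB", "node", internal = list("A", "B"), external = list("C")),
    phylo_definition("AD", "node", internal = list("A", "D"), external = list("C")))
  runs <- list(run1 = list(consensus = t_ab, trees = list(t_ab, t_ab, t_ac)),
               run2 = list(consensus = t_ac, trees = list(t_ac)))
  rep <- weak_spot_report(defs, runs)
  expect_equal(rep$status["AB", "run1"], "APPLIES")
  expect_equal(rep$status["AB", "run2"], "SELF_DESTRUCTS")
  expect_equal(rep$summary[["AB"]], "STRATEGY_DEPENDENT")
  expect_equal(rep$summary[["AD"]], "UNSUPPORTED")
  expect_equal(rep$applies_fraction["AB", "run1"], 2 / 3)
  # single-run input degenerates to one column
  rep1 <- weak_spot_report(defs, runs["run1"])
  expect_equal(ncol(rep1$status), 1L)
  tsv <- withr::local_tempfile()
  write_weak_spot_tsv(rep, tsv)
  expect_true(file.exists(tsv))
})
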