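test_that("presence matrix is built from detected pairs per species", {
  ann <- builtin_fixture("human_table1")
  pairs <- detect_pairs(ann)
  pm <- build_presence_matrix(list(H_sapiens = pairs, Other = pairs[0, ]),
                              fig1_defs)
  expect_identical(unname(pm[, "H_sapiens"]),
                   c("present", "present", "present"))
  expect_identical(unname(pm[, "Other"]), c("absent", "absent", "absent"))
  pm_u <- build_presence_matrix(list(Other = pairs[0, ]), fig1_defs,
                                missing_policy = "unknown")
  expect_identical(unname(pm_u[, "Other"]),
                   c("unknown", "unknown", "unknown"))
  bad <- pairs
  bad$group_pdi <- "mystery"
  expect_error(build_presence_matrix(list(x = bad), fig1_defs),
               "no cluster label")
})

test_that("the primordial cluster gain dates to the cnidarian+bilaterian
           ancestor with Drosophila in the loss set", {
  pm <- builtin_fixture("species_presence_fig1")
  tr <- builtin_fixture("species_tree_fig1")
  rec <- dollo_reconstruct(pm, tr, "primordial")
  expect_setequal(rec$gain$tips, setdiff(tr$tip.label, "A_queenslandica"))
  loss_tips <- lapply(rec$losses, `[[`, "tips")
  expect_identical(length(loss_tips), 1L)
  expect_identical(loss_tips[[1]], "D_melanogaster")
  # sponge stays outside the gain: ancestral root state is absent
  root <- length(tr$tip.label) + 1L
  expect_identical(unname(rec$ancestral_state[as.character(root)]),
                   "absent")
})

test_that("all-present leaves put the gain at the root with zero losses", {
  tr <- read_newick_text("((A,B),(C,D));")
  pm <- presence_matrix(matrix("present", 1, 4,
                               dimnames = list("X", c("A", "B", "C", "D"))))
  rec <- dollo_reconstruct(pm, tr, "X")
  expect_setequal(rec$gain$tips, c("A", "B", "C", "D"))
  expect_identical(length(rec$losses), 0L)
})

test_that("unknown leaves constrain nothing", {
  tr <- read_newick_text("((A,B),(C,D));")
  m <- matrix(c("present", "unknown", "present", "unknown"), 1, 4,
              dimnames = list("X", c("A", "B", "C", "D")))
  rec <- dollo_reconstruct(presence_matrix(m), tr, "X")
  expect_identical(length(rec$losses), 0L)
  m2 <- m
  m2[1, "D"] <- "absent"
  rec2 <- dollo_reconstruct(presence_matrix(m2), tr, "X")
  expect_identical(length(rec2$losses), 1L)
  expect_identical(rec2$losses[[1]]$tips, "D")
  expect_error(
    dollo_reconstruct(presence_matrix(
      matrix("absent", 1, 4, dimnames = dimnames(m))), tr, "X"),
    "no present leaf")
})

test_that("dollo loss counts equal the exhaustive single-gain minimum", {
  # complete sweep: every labelled rooted binary 4-leaf topology x every
  # non-trivial present/absent assignment, plus unknowns sprinkled in
  tips <- c("A", "B", "C", "D")
  topologies <- all_rooted_topologies(tips)
  expect_identical(length(topologies), 15L)
  states_of <- function(code) {
    s <- c("absent", "present")[(bitwAnd(code, 2^(0:3)) > 0) + 1]
    stats::setNames(s, tips)
  }
  for (nwk in topologies) {
    tr <- read_newick_text(paste0(nwk, ";"))
    for (code in 1:15) {
      states <- states_of(code)
      m <- matrix(states, 1, 4, dimnames = list("X", tips))
      rec <- dollo_reconstruct(presence_matrix(m), tr, "X")
      expect_identical(length(rec$losses),
                       as.integer(oracle_dollo_min_losses(tr, states)))
    }
  }
  # seeded random instances at 6-8 leaves with all three states
  set.seed(46)
  for (rep in 1:40) {
    n <- sample(6:8, 1)
    tr <- random_binary_tree(n)
    states <- stats::setNames(
      sample(c("present", "absent", "unknown"), n, replace = TRUE),
      tr$tip.label)
    if (!any(states == "present")) states[sample(n, 1)] <- "present"
    m <- matrix(states, 1, n, dimnames = list("X", tr$tip.label))
    rec <- dollo_reconstruct(presence_matrix(m), tr, "X")
    expect_identical(length(rec$losses),
                     as.integer(oracle_dollo_min_losses(tr, states)))
  }
})

test_that("losses never lie on a path from the gain to a present leaf and
           adding a present leaf only moves the gain rootward", {
  set.seed(47)
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    tr <- random_binary_tree(n)
    states <- stats::setNames(
      sample(c("present", "absent"), n, replace = TRUE), tr$tip.label)
    if (sum(states == "present") == 0) states[sample(n, 1)] <- "present"
    m <- matrix(states, 1, n, dimnames = list("X", tr$tip.label))
    rec <- dollo_reconstruct(presence_matrix(m), tr, "X")
    present <- names(states)[states == "present"]
    for (loss in rec$losses) {
      expect_identical(intersect(loss$tips, present), character(0))
    }
    absent <- names(states)[states == "absent"]
    if (length(absent) > 0) {
      flip <- sample(absent, 1)
      states2 <- states
      states2[flip] <- "present"
      m2 <- matrix(states2, 1, n, dimnames = list("X", tr$tip.label))
      rec2 <- dollo_reconstruct(presence_matrix(m2), tr, "X")
      # old gain clade is contained in the new one
      expect_true(all(rec$gain$tips %in% rec2$gain$tips))
    }
  }
})

test_that("reconciling the paralog-cluster tree yields two duplications at
           the vertebrate ancestor", {
  tr <- builtin_fixture("species_tree_fig1")
  fx <- builtin_fixture("cluster_tree_fig2")
  rec <- reconcile_duplications(fx$tree, tr, fx$species_map)
  expect_identical(rec$duplication_count, 2L)
  vert <- node_by_tips(tr, c("C_milii", "L_oculatus", "H_sapiens"))
  expect_true(all(rec$lca_map[rec$duplication_nodes] == vert))
  # the alternative sister resolution of the three clusters agrees
  alt <- read_newick_text(paste0(
    "((PDIA2-RhoGDIg@C_milii,(PDIA2-RhoGDIg@L_oculatus,",
    "PDIA2-RhoGDIg@H_sapiens)),",
    "((PDIA1-RhoGDIa@C_milii,(PDIA1-RhoGDIa@L_oculatus,",
    "PDIA1-RhoGDIa@H_sapiens)),PDIA8-RhoGDIb@H_sapiens));"))
  map <- stats::setNames(sub("^.*@", "", alt$tip.label), alt$tip.label)
  rec_alt <- reconcile_duplications(alt, tr, map)
  expect_identical(rec_alt$duplication_count, 2L)
  expect_true(all(rec_alt$lca_map[rec_alt$duplication_nodes] == vert))
})

test_that("a cluster tree congruent with the species tree has none", {
  sp <- read_newick_text("((A,B),(C,D));")
  cl <- read_newick_text("((gA,gB),(gC,gD));")
  map <- stats::setNames(c("A", "B", "C", "D"), c("gA", "gB", "gC", "gD"))
  expect_identical(reconcile_duplications(cl, sp, map)$duplication_count, 0L)
})

test_that("reconciliation rejects polytomies and unmapped leaves", {
  sp <- read_newick_text("((A,B),(C,D));")
  poly <- read_newick_text("((gA,gB,gC),gD);")
  map <- stats::setNames(c("A", "B", "C", "D"), c("gA", "gB", "gC", "gD"))
  expect_error(reconcile_duplications(poly, sp, map), "polytom")
  cl <- read_newick_text("((gA,gB),gC);")
  expect_error(reconcile_duplications(cl, sp, map[c("gA", "gB")]),
               "without species mapping")
  sp_poly <- read_newick_text("((A,B,C),D);")
  expect_error(reconcile_duplications(cl, sp_poly, map), "polytom")
})

test_that("duplication sets match the path-intersection oracle and are
           invariant under child swaps and species relabeling", {
  set.seed(48)
  for (rep in 1:30) {
    ns <- sample(3:6, 1)
    sp <- random_binary_tree(ns)
    sp$tip.label <- paste0("s", seq_len(ns))
    nc <- sample(2:8, 1)
    cl <- random_binary_tree(nc)
    cl$tip.label <- paste0("g", seq_len(nc))
    map <- stats::setNames(sample(sp$tip.label, nc, replace = TRUE),
                           cl$tip.label)
    rec <- reconcile_duplications(cl, sp, map)
    expect_setequal(rec$duplication_nodes, oracle_reconcile(cl, sp, map))
    # swap the two children of the cluster-tree root
    swapped <- ape::rotate(cl, length(cl$tip.label) + 1L)
    rec_sw <- reconcile_duplications(swapped, sp, map)
    expect_identical(rec_sw$duplication_count, rec$duplication_count)
    # bijective species relabeling
    perm <- sample(sp$tip.label)
    relabel <- stats::setNames(perm, sp$tip.label)
    sp2 <- sp
    sp2$tip.label <- unname(relabel[sp$tip.label])
    map2 <- stats::setNames(unname(relabel[map]), names(map))
    rec_rl <- reconcile_duplications(cl, sp2, map2)
    expect_identical(rec_rl$duplication_count, rec$duplication_count)
  }
})

test_that("disruption classification audits absence into its mode", {
  crit <- pair_criteria()
  # same chromosome, far beyond the window (the fly arrangement)
  fly <- make_annotation(
    make_gene("fly_pdi", 1e6, 1.01e6, "+", species = "fly",
              group = "PDIA", family = "PDI"),
    make_gene("fly_gdi", 2.5e6, 2.51e6, "+", species = "fly",
              group = "GDIA", family = "RhoGDI"))
  call <- classify_disruption("fly", "X", fly, c("PDIA", "GDIA"), crit)
  expect_identical(call$mode, "unlinked_same_scaffold")
  # different scaffolds
  split_ann <- make_annotation(
    make_gene("a", 100, 200, scaffold = "s1", species = "sp",
              group = "PDIA", family = "PDI"),
    make_gene("b", 100, 200, scaffold = "s2", species = "sp",
              group = "GDIA", family = "RhoGDI"))
  expect_identical(
    classify_disruption("sp", "X", split_ann, c("PDIA", "GDIA"))$mode,
    "unlinked_different_scaffold")
  # one member unannotated: lost under policy absent, unknown otherwise
  coel <- make_annotation(
    make_gene("gdib", 100, 200, species = "coel", group = "RhoGDIb",
              family = "RhoGDI"))
  expect_identical(
    classify_disruption("coel", "X", coel, c("PDIA8", "RhoGDIb"))$mode,
    "one_gene_lost")
  expect_identical(
    classify_disruption("coel", "X", coel, c("PDIA8", "RhoGDIb"),
                        missing_policy = "unknown")$mode,
    "unknown")
  expect_identical(
    classify_disruption("coel", "X", coel, c("PDIA8", "PDIA1"))$mode,
    "both_genes_lost")
  # intact pair
  ok <- make_annotation(
    make_gene("p", 1000, 2000, "+", species = "sp", group = "PDIA",
              family = "PDI"),
    make_gene("g", 2200, 2800, "+", species = "sp", group = "GDIA",
              family = "RhoGDI"))
  expect_identical(
    classify_disruption("sp", "X", ok, c("PDIA", "GDIA"))$mode, "intact")
})

test_that("node ages are annotations, retrieved or unknown", {
  tr <- builtin_fixture("species_tree_fig1")
  expect_identical(
    date_node(tr, setdiff(tr$tip.label, "A_queenslandica")), 820)
  expect_identical(date_node(tr, "H_sapiens"), "unknown")
  tr2 <- set_node_age(tr, "H_sapiens", 0)
  expect_identical(date_node(tr2, "H_sapiens"), 0)
  expect_error(date_node(tr, 99L), "not in tree")
  expect_error(date_node(tr, c("H_sapiens", "nope")), "not in tree")
})
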