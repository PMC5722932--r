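fig1_tree <- function() builtin_fixture("species_tree_fig1")
vert_tips <- c("C_milii", "L_oculatus", "H_sapiens")
gain_clade <- function(tr) setdiff(tr$tip.label, "A_queenslandica")

noise_free_params <- function(seed = 1) {
  tr <- fig1_tree()
  sim_params(gain_tips = gain_clade(tr),
             duplication_tips = list(vert_tips, vert_tips),
             seed = seed)
}

sim_defs <- function(sim) {
  cl <- attr(sim$truth, "clusters")
  stats::setNames(
    lapply(cl, function(c) c(paste0("PDI_", c), paste0("GDI_", c))), cl)
}

test_that("zero-noise replay: every gain-clade leaf carries three intact
           pairs, leaves outside carry none", {
  tr <- fig1_tree()
  sim <- simulate_gene_order(tr, noise_free_params(seed = 3))
  inside_vert <- vert_tips
  for (sp in tr$tip.label) {
    pairs <- detect_pairs(sim$annotations[[sp]])
    expected <- if (sp %in% inside_vert) 3L
                else if (sp %in% gain_clade(tr)) 1L else 0L
    expect_identical(nrow(pairs), expected, label = sp)
  }
})

test_that("a fixed seed reproduces the simulation exactly", {
  tr <- fig1_tree()
  p <- sim_params(gain_tips = gain_clade(tr),
                  duplication_tips = list(vert_tips),
                  loss_rate = 0.1, inversion_rate = 0.1,
                  translocation_rate = 0.1,
                  background_insertion_rate = 0.1, seed = 99)
  s1 <- simulate_gene_order(tr, p)
  s2 <- simulate_gene_order(tr, p)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  expect_identical(s1$truth_matrix, s2$truth_matrix)
  s3 <- simulate_gene_order(
    tr, sim_params(gain_tips = gain_clade(tr),
                   duplication_tips = list(vert_tips),
                   loss_rate = 0.1, inversion_rate = 0.1,
                   translocation_rate = 0.1,
                   background_insertion_rate = 0.1, seed = 100))
  expect_false(identical(as.data.frame(s1$truth), as.data.frame(s3$truth)))
})

test_that("simulator output keeps gene IDs unique and annotations sorted", {
  tr <- fig1_tree()
  p <- sim_params(gain_tips = gain_clade(tr),
                  duplication_tips = list(vert_tips),
                  loss_rate = 0.2, inversion_rate = 0.3,
                  translocation_rate = 0.2,
                  background_insertion_rate = 0.5, seed = 17)
  sim <- simulate_gene_order(tr, p)
  all_ids <- unlist(lapply(sim$annotations, `[[`, "gene_id"))
  expect_identical(anyDuplicated(all_ids), 0L)
  for (ann in sim$annotations) {
    ord <- order(ann$scaffold, ann$start)
    expect_identical(ord, seq_len(nrow(ann)))
    expect_true(all(ann$start <= ann$end))
  }
  expect_setequal(sim$ortholog_table$gene_id, all_ids)
})

test_that("invalid branch references and rates are rejected", {
  tr <- fig1_tree()
  expect_error(
    sim_params(gain_tips = "H_sapiens", loss_rate = -1), "non-negative")
  expect_error(
    simulate_gene_order(tr, sim_params(
      gain_tips = vert_tips,
      duplication_tips = list(c("D_melanogaster", "C_elegans")))),
    "at or below the gain")
  expect_error(
    simulate_gene_order(tr, sim_params(
      gain_tips = vert_tips,
      duplication_tips = list(c("N_vectensis", "H_sapiens")))),
    "no node subtends")
  expect_error(
    simulate_gene_order(tr, sim_params(gain_tips = c("H_sapiens", "nope"))),
    "not in tree")
  expect_error(
    simulate_gene_order(tr, sim_params(gain_tips = tr$tip.label)),
    "root has no stem")
})

test_that("pair survival under pure loss matches the branch-length
           expectation and an independent Monte-Carlo of the process", {
  tr <- fig1_tree()  # unit branch lengths
  rate <- 0.05
  gain <- gain_clade(tr)
  n_rep <- 50
  surv <- matrix(FALSE, n_rep, length(gain),
                 dimnames = list(NULL, gain))
  for (r in seq_len(n_rep)) {
    sim <- simulate_gene_order(tr, sim_params(
      gain_tips = gain, loss_rate = rate, seed = 1000 + r))
    surv[r, ] <- sim$truth_matrix["C1", gain] == "present"
  }
  # path length (in branches) from the gain branch, inclusive, to each leaf
  gain_node <- node_by_tips(tr, gain)
  ntip <- length(tr$tip.label)
  parent_of <- integer(ntip + tr$Nnode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  path_len <- vapply(gain, function(sp) {
    nd <- match(sp, tr$tip.label)
    n <- 0L
    while (nd != gain_node) {
      n <- n + 1L
      nd <- parent_of[nd]
    }
    n + 1L  # the gain branch itself carries post-gain loss events
  }, integer(1))
  set.seed(2026)
  mc <- vapply(seq_along(gain), function(i) {
    mean(rpois(20000, rate * path_len[i]) == 0)
  }, numeric(1))
  for (i in seq_along(gain)) {
    p_hat <- mean(surv[, gain[i]])
    p_exp <- exp(-rate * path_len[i])
    tol <- 4 * sqrt(p_exp * (1 - p_exp) / n_rep) + 0.01
    expect_lt(abs(p_hat - p_exp), tol)
    expect_lt(abs(p_hat - mc[i]), tol)
  }
})

test_that("replay of minimal hand-built histories", {
  tr <- read_newick_text("((A,B),(C,D));")
  gain_node <- node_by_tips(tr, c("A", "B"))
  hist1 <- data.frame(type = "gain", node = gain_node, cluster = "C1",
                      gene = NA, disrupts = "", restores = "C1",
                      stringsAsFactors = FALSE)
  attr(hist1, "clusters") <- "C1"
  class(hist1) <- c("event_history", "data.frame")
  pm <- replay_truth(hist1, tr)
  expect_identical(unname(pm["C1", ]),
                   c("present", "present", "absent", "absent"))
  hist2 <- rbind(hist1, data.frame(
    type = "loss", node = match("B", tr$tip.label), cluster = "C1",
    gene = "C1_pdi", disrupts = "C1", restores = "",
    stringsAsFactors = FALSE))
  attr(hist2, "clusters") <- "C1"
  class(hist2) <- c("event_history", "data.frame")
  pm2 <- replay_truth(hist2, tr)
  expect_identical(unname(pm2["C1", ]),
                   c("present", "absent", "absent", "absent"))
  # loss of a cluster never gained is inconsistent
  bad <- hist2[2, , drop = FALSE]
  attr(bad, "clusters") <- "C1"
  class(bad) <- c("event_history", "data.frame")
  expect_error(replay_truth(bad, tr), "inconsistent history")
})

test_that("replayed matrices equal the simulator's truth and a brute-force
           propagation across random histories", {
  set.seed(54)
  for (rep in 1:100) {
    tr <- random_binary_tree(sample(4:8, 1))
    root <- length(tr$tip.label) + 1L
    gain <- tree_tips_below(
      tr, sample(setdiff(seq_len(length(tr$tip.label) + tr$Nnode), root), 1))
    dup <- if (length(gain) > 1 && runif(1) < 0.5) list(gain) else list()
    p <- sim_params(gain_tips = gain, duplication_tips = dup,
                    loss_rate = runif(1, 0, 0.3),
                    inversion_rate = runif(1, 0, 0.3),
                    translocation_rate = runif(1, 0, 0.3),
                    background_insertion_rate = runif(1, 0, 0.3),
                    n_background_genes = 8L,
                    seed = sample.int(1e6, 1))
    sim <- simulate_gene_order(tr, p)
    replayed <- replay_truth(sim$truth, tr)
    truth <- sim$truth_matrix
    expect_identical(
      unclass(replayed)[rownames(truth), colnames(truth), drop = FALSE],
      unclass(truth)[, , drop = FALSE])
    oracle <- oracle_replay(sim$truth, tr)
    expect_identical(
      unclass(replayed)[rownames(oracle), colnames(oracle), drop = FALSE],
      oracle)
  }
})

test_that("end-to-end recovery: with no rearrangement the gain branch and
           duplication count are recovered in every seeded replicate", {
  tr <- fig1_tree()
  gain <- gain_clade(tr)
  n_ok_gain <- 0L
  n_ok_dup <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    sim <- simulate_gene_order(tr, noise_free_params(seed = 2000 + r))
    pbs <- lapply(sim$annotations, detect_pairs)
    pm <- build_presence_matrix(pbs, sim_defs(sim))
    rec <- dollo_reconstruct(pm, tr, "C1")
    if (setequal(rec$gain$tips, gain)) n_ok_gain <- n_ok_gain + 1L
    ct <- true_cluster_tree(sim)
    dup <- reconcile_duplications(ct$tree, tr, ct$species_map)
    if (dup$duplication_count == 2L) n_ok_dup <- n_ok_dup + 1L
  }
  expect_identical(n_ok_gain, n_rep)
  expect_identical(n_ok_dup, n_rep)
})

test_that("under pure loss the Dollo loss count never exceeds the
           simulated number of loss events", {
  tr <- fig1_tree()
  gain <- gain_clade(tr)
  for (r in 1:25) {
    sim <- simulate_gene_order(tr, sim_params(
      gain_tips = gain, loss_rate = 0.15, seed = 3000 + r))
    pbs <- lapply(sim$annotations, detect_pairs)
    pm <- build_presence_matrix(pbs, sim_defs(sim))
    if (!any(pm["C1", ] == "present")) next
    rec <- dollo_reconstruct(pm, tr, "C1")
    n_sim_losses <- sum(sim$truth$type == "loss" &
                        sim$truth$disrupts != "")
    expect_lte(length(rec$losses), n_sim_losses)
  }
})

test_that("the truth-implied cluster tree has one leaf per retained
           cluster-species combination", {
  tr <- fig1_tree()
  sim <- simulate_gene_order(tr, noise_free_params(seed = 5))
  ct <- true_cluster_tree(sim)
  tm <- sim$truth_matrix
  expect_identical(length(ct$tree$tip.label), sum(tm == "present"))
  expect_true(all(ct$species_map %in% tr$tip.label))
})
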