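test_that("read_newick parses rooted and multifurcating trees", {
  t1 <- read_newick(text = "((A,B),(C,D));")
  expect_identical(ape::Ntip(t1), 4L)
  expect_identical(ape::Nnode(t1), 3L)
  t2 <- read_newick(text = "(A,B,C);")
  expect_identical(ape::Ntip(t2), 3L)
  expect_identical(ape::Nnode(t2), 1L)
  t3 <- read_newick(text = "(('sp one',B),C);")
  expect_true("sp one" %in% t3$tip.label)
  expect_error(read_newick(text = "((A,B),(A,C));"), "duplicate")
})

test_that("Fitch counts match enumeration on the worked four-tip cases", {
  tr <- read_newick(text = "((A,B),(C,D));")
  one <- fitch_parsimony(tr, c(A = "present", B = "present",
                               C = "absent", D = "absent"))
  expect_identical(one$min_changes, 1L)
  two <- fitch_parsimony(tr, c(A = "present", B = "absent",
                               C = "present", D = "absent"))
  expect_identical(two$min_changes, 2L)
  zero <- fitch_parsimony(tr, c(A = "present", B = "present",
                                C = "present", D = "present"))
  expect_identical(zero$min_changes, 0L)
  expect_error(fitch_parsimony(tr, c(A = "present")), "without a state")
})

test_that("Fitch equals brute-force enumeration on random trees (<= 8 tips)", {
  set.seed(20180508)
  for (case in 1:200) {
    n <- sample(2:8, 1)
    tr <- random_tree(n)
    st <- setNames(sample(c("present", "absent"), n, replace = TRUE),
                   tr$tip.label)
    expect_identical(fitch_parsimony(tr, st)$min_changes,
                     as.integer(brute_force_parsimony(tr, st)),
                     info = paste("case", case))
  }
})

test_that("Fitch agrees with phangorn on larger random trees", {
  set.seed(99)
  for (case in 1:20) {
    n <- sample(10:40, 1)
    tr <- ape::rtree(n)
    st <- setNames(sample(c("present", "absent"), n, replace = TRUE),
                   tr$tip.label)
    dat <- phangorn::phyDat(
      matrix(ifelse(st[tr$tip.label] == "present", "a", "c"), ncol = 1,
             dimnames = list(tr$tip.label, NULL)),
      type = "USER", levels = c("a", "c"))
    expect_identical(fitch_parsimony(tr, st)$min_changes,
                     as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("min_changes is 0 iff all tips share one state", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    tr <- random_tree(n)
    st <- setNames(sample(c("present", "absent"), n, replace = TRUE),
                   tr$tip.label)
    mc <- fitch_parsimony(tr, st)$min_changes
    expect_identical(mc == 0L, length(unique(st)) == 1L)
    # minority-state tip count is an upper bound
    expect_lte(mc, min(table(factor(st, c("present", "absent")))))
  }
})

test_that("consistent relabeling leaves min_changes unchanged", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- random_tree(n)
    st <- setNames(sample(c("present", "absent"), n, replace = TRUE),
                   tr$tip.label)
    mc1 <- fitch_parsimony(tr, st)$min_changes
    relabel <- setNames(paste0("x", seq_len(n)), tr$tip.label)
    tr2 <- tr; tr2$tip.label <- unname(relabel[tr$tip.label])
    st2 <- setNames(unname(st), unname(relabel[names(st)]))
    expect_identical(fitch_parsimony(tr2, st2)$min_changes, mc1)
  }
})

test_that("loss/gain classification follows the ancestral-present polarity", {
  tr <- read_newick(text = "((A,B),(C,D));")
  lg <- count_losses_gains(tr, c(A = "present", B = "present",
                                 C = "absent", D = "absent"))
  expect_identical(lg$n_losses, 1L)
  expect_identical(lg$n_gains, 0L)
  expect_identical(lg$root_state, "present")

  allp <- count_losses_gains(tr, c(A = "present", B = "present",
                                   C = "present", D = "present"))
  expect_identical(c(allp$n_losses, allp$n_gains), c(0L, 0L))

  t8 <- read_newick(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  st <- setNames(rep("present", 8), LETTERS[1:8])
  st[["E"]] <- "absent"
  lg8 <- count_losses_gains(t8, st)
  expect_identical(lg8$n_losses, 1L)
  expect_identical(lg8$n_gains, 0L)
})

test_that("losses + gains always equals the parsimony minimum", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    tr <- random_tree(n)
    st <- setNames(sample(c("present", "absent"), n, replace = TRUE),
                   tr$tip.label)
    for (assume in c("present", "infer")) {
      lg <- count_losses_gains(tr, st, assume)
      expect_identical(lg$n_losses + lg$n_gains, lg$min_changes)
    }
  }
})

test_that("character maps tie matrix columns to the tree", {
  m <- toy_matrix()
  tr <- read_newick(text = "((m1,(m2,m3)),(f1,f2));")
  cm <- character_map(tr, m, "pbsA")
  expect_identical(cm$min_changes, 1L)
  expect_identical(cm$n_losses, 1L)
  td <- tidy(cm)
  expect_identical(td$gene, "pbsA")
  expect_identical(td$n_losses, 1L)

  tab <- map_genes(tr, m)
  expect_identical(nrow(tab), length(matrix_genes(m)))
  expect_true(all(tab$min_changes == tab$n_losses + tab$n_gains))

  f <- withr::local_tempfile(fileext = ".nwk")
  write_character_map(cm, f)
  back <- ape::read.tree(f)
  expect_identical(sort(back$node.label),
                   sort(unname(cm$internal_states)))

  expect_error(character_map(ape::drop.tip(tr, "f2"), m, "pbsA"),
               "missing from tree")
})

test_that("clade summaries report planted clade-wide losses at fraction 0", {
  # one clade of 3 tips lacking the gene entirely, mixed habitats
  tr <- read_newick(text = "(((a,b),c),((d,e),f));")
  inv <- list(a = c("g1"), b = c("g1"), c = c("g1"),
              d = c("g2"), e = c("g2"), f = c("g2"))
  hab <- c(a = "marine", b = "marine", c = "marine",
           d = "marine", e = "freshwater", f = "freshwater")
  m <- build_matrix(inv, hab)
  cs <- clade_presence_summary(tr, m, genes = "g1")
  # the (d,e) clade and the ((d,e),f) clade both lack g1 entirely
  zero_nodes <- cs$node[cs$presence_fraction == 0]
  expect_gte(length(zero_nodes), 2L)
  def_clade <- cs[cs$n_tips == 3 & cs$presence_fraction == 0, ]
  expect_identical(nrow(def_clade), 1L)
  expect_identical(def_clade$n_marine, 1L)       # mixed-habitat clade
  expect_identical(def_clade$n_freshwater, 2L)
  root_row <- cs[cs$n_tips == 6, ]
  expect_equal(root_row$presence_fraction, 0.5)
})

test_that("branch-mode simulation produces clustered losses the map recovers", {
  genes <- tibble::tibble(symbol = "hab1", loss_prob_marine = 0.01,
                          loss_prob_freshwater = 1)
  cfg <- sim_config(n_marine = 10, n_freshwater = 10, n_brackish = 0,
                    tree_model = "yule", habitat_transition_rate = 0.2,
                    genes = genes, n_core = 2, seed = 17)
  tr <- simulate_tree(cfg)
  hab <- simulate_habitat(tr, cfg)
  sim <- simulate_gene_loss(tr, hab, cfg, mode = "branch")
  tab <- map_genes(tr, sim$matrix, "hab1")
  n_absent <- sum(!sim$matrix$hab1)
  # irreversible branchwise loss clusters events: strictly fewer changes
  # than absent tips whenever losses are shared, never gains
  expect_identical(tab$n_gains, 0L)
  expect_lte(tab$min_changes, n_absent)
})
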