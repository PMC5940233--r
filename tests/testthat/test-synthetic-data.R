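test_that("tree simulation: star shape, Yule arithmetic, determinism", {
  cfg <- sim_config(n_marine = 3, n_freshwater = 2, n_brackish = 0, seed = 1)
  star <- simulate_tree(cfg)
  expect_identical(ape::Ntip(star), 5L)
  expect_identical(ape::Nnode(star), 1L)            # root with 5 children
  expect_true(all(star$edge.length == 1))

  ycfg <- sim_config(n_marine = 30, n_freshwater = 20, n_brackish = 0,
                     tree_model = "yule", seed = 4)
  yule <- simulate_tree(ycfg)
  expect_identical(ape::Ntip(yule), 50L)
  expect_identical(ape::Nnode(yule), 49L)           # 49 internal bifurcations

  expect_equal(simulate_tree(ycfg), simulate_tree(ycfg))
  expect_error(simulate_tree(sim_config(n_marine = 1, n_freshwater = 0,
                                        n_brackish = 0)), "2 tips")
})

test_that("star-tree habitats hit the configured composition exactly", {
  cfg <- sim_config(n_marine = 3, n_freshwater = 2, n_brackish = 1, seed = 2)
  tr <- simulate_tree(cfg)
  hab <- simulate_habitat(tr, cfg)
  tab <- table(as.character(hab))
  expect_identical(as.integer(tab[c("brackish", "freshwater", "marine")]),
                   c(1L, 2L, 3L))
  # reproducible under the seed
  expect_identical(as.character(hab),
                   as.character(simulate_habitat(tr, cfg)))
})

test_that("zero transition rate keeps every tip marine on a Yule tree", {
  cfg <- sim_config(n_marine = 10, n_freshwater = 0, n_brackish = 0,
                    tree_model = "yule", habitat_transition_rate = 0,
                    seed = 3)
  hab <- simulate_habitat(simulate_tree(cfg), cfg)
  expect_true(all(hab == "marine"))
})

test_that("high transition rate approaches the 50/50 stationary mix", {
  # symmetric two-state chain: stationary distribution is (1/2, 1/2)
  fresh_frac <- purrr::map_dbl(1:60, function(s) {
    cfg <- sim_config(n_marine = 20, n_freshwater = 0, n_brackish = 0,
                      tree_model = "yule", habitat_transition_rate = 50,
                      seed = s)
    mean(simulate_habitat(simulate_tree(cfg), cfg) == "freshwater")
  })
  expect_lt(abs(mean(fresh_frac) - 0.5), 0.05)
})

test_that("gene loss honours the per-habitat probabilities", {
  # degenerate probabilities
  sure <- sim_config(n_marine = 5, n_freshwater = 5, n_brackish = 0,
                     genes = tibble::tibble(symbol = "keep",
                                            loss_prob_marine = 0,
                                            loss_prob_freshwater = 0),
                     n_core = 0, seed = 6)
  tr <- simulate_tree(sure)
  sim <- simulate_gene_loss(tr, simulate_habitat(tr, sure), sure)
  expect_true(all(sim$matrix$keep))

  gone <- sim_config(n_marine = 5, n_freshwater = 5, n_brackish = 0,
                     genes = tibble::tibble(
                       symbol = c("gone", "keep"),
                       loss_prob_marine = c(1, 0),
                       loss_prob_freshwater = c(1, 0)),
                     n_core = 0, seed = 6)
  expect_warning(
    sim2 <- simulate_gene_loss(tr, simulate_habitat(tr, gone), gone),
    "dropped")
  expect_false("gone" %in% matrix_genes(sim2$matrix))

  # Monte-Carlo check of the binomial expectation (loss 0.9 freshwater)
  mean_absent <- purrr::map_dbl(1:150, function(s) {
    cfg <- sim_config(n_marine = 20, n_freshwater = 16, n_brackish = 0,
                      genes = tibble::tibble(symbol = "hab",
                                             loss_prob_marine = 0.05,
                                             loss_prob_freshwater = 0.9),
                      n_core = 1, core_loss = 0, seed = s)
    t <- simulate_tree(cfg)
    h <- simulate_habitat(t, cfg)
    mm <- simulate_gene_loss(t, h, cfg)$matrix
    mean(!mm$hab[mm$habitat == "freshwater"])
  })
  expect_lt(abs(mean(mean_absent) - 0.9), 0.02)
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 123, n_marine = 10, n_freshwater = 5,
                    n_brackish = 1, n_core = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("emitted spacer GC tracks the configured fraction", {
  f <- withr::local_tempfile(fileext = ".gb")
  # one short CDS, everything else spacer, ~10 kb total
  emit_toy_genbank("GC check", "psbA", seed = 44, gc = 0.3,
                   cds_length = 300, n_trna = 0, n_rrna = 0, path = f)
  g <- read_genbank_record(f)
  # composition dominated by the configured spacers and near-uniform CDS;
  # check the spacer region explicitly
  feat <- g$features[g$features$kind == "CDS", ]
  spacer_seq <- paste0(substr(g$sequence, 1, feat$start),
                       substr(g$sequence, feat$end + 1, nchar(g$sequence)))
  chars <- strsplit(spacer_seq, "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.3), 0.1)  # short spacers: loose binomial bound

  big <- purrr::map_dbl(1:20, function(s) {
    ff <- tempfile(fileext = ".gb")
    on.exit(unlink(ff))
    emit_toy_genbank("GC big", "psbA", seed = s, gc = 0.3, path = ff)
    gg <- read_genbank_record(ff)
    chars <- strsplit(gg$sequence, "")[[1]]
    mean(chars %in% c("G", "C"))
  })
  expect_lt(abs(mean(big) - 0.3), 0.02)
})

test_that("the bundle writes a coherent plain-text world", {
  cfg <- sim_config(n_marine = 8, n_freshwater = 6, n_brackish = 1,
                    seed = 77, n_core = 5)
  dir <- withr::local_tempdir()
  b <- simulate_bundle(cfg, dir)
  expect_true(all(file.exists(unlist(b$paths))))
  m <- read_matrix(b$paths$matrix)
  expect_equal(as.data.frame(m), as.data.frame(b$matrix))
  tr <- read_newick(b$paths$tree)
  expect_setequal(tr$tip.label, m$species_id)
  truth <- jsonlite::read_json(b$paths$truth, simplifyVector = TRUE)
  expect_identical(sort(names(truth$planted_isotypes)),
                   sort(c("prot_hmox1", "prot_hmox2", "prot_pbsa")))
})
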