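#' Simulation configuration for the synthetic survey world
#'
#' The generator's defaults emulate the red-algal plastid survey the
#' screen was designed for: 127 species (109 marine, 16 freshwater, 2
#' brackish), four habitat-linked genes whose loss probabilities echo the
#' printed pbsA retention pattern (about 14% of marine and 75% of
#' freshwater species lack the gene), and a backdrop of core plastid
#' genes under a low uniform loss probability. Tips are independent on
#' the default star tree; a Yule tree with branchwise habitat evolution
#' is available for phylogenetically clustered scenarios.
#'
#' @param n_marine,n_freshwater,n_brackish Tip counts per habitat
#'   (star trees use them exactly; Yule trees draw habitats from the
#'   Markov process and only `n_brackish` is imposed).
#' @param tree_model `"star"` or `"yule"`.
#' @param birth_rate Yule birth rate (per unit time).
#' @param habitat_transition_rate Symmetric per-unit-length rate of the
#'   two-state marine/freshwater Markov process on Yule branches.
#' @param genes Tibble with columns `symbol`, `loss_prob_marine`,
#'   `loss_prob_freshwater`.
#' @param n_core Number of background core genes (uniform loss).
#' @param core_loss Loss probability of core genes in both habitats.
#' @param seed Integer seed fixing all randomness of the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_marine = 109, n_freshwater = 16, n_brackish = 2,
                       tree_model = c("star", "yule"), birth_rate = 1,
                       habitat_transition_rate = 0.3,
                       genes = NULL, n_core = 30, core_loss = 0.02,
                       seed = 1) {
  tree_model <- match.arg(tree_model)
  if (n_marine < 0 || n_freshwater < 0 || n_brackish < 0) {
    abort("tip counts must be non-negative")
  }
  if (habitat_transition_rate < 0) abort("transition rate must be >= 0")
  if (is.null(genes)) {
    genes <- tibble(
      symbol = c("pbsA", "ycf34", "ycf35", "ycf46"),
      loss_prob_marine = 0.14,
      loss_prob_freshwater = 0.75
    )
  }
  if (n_core > 0) {
    genes <- bind_rows(genes, tibble(
      symbol = sprintf("core%02d", seq_len(n_core)),
      loss_prob_marine = core_loss,
      loss_prob_freshwater = core_loss
    ))
  }
  if (any(genes$loss_prob_marine < 0 | genes$loss_prob_marine > 1 |
          genes$loss_prob_freshwater < 0 | genes$loss_prob_freshwater > 1)) {
    abort("loss probabilities must lie in [0, 1]")
  }
  structure(
    list(n_marine = n_marine, n_freshwater = n_freshwater,
         n_brackish = n_brackish, tree_model = tree_model,
         birth_rate = birth_rate,
         habitat_transition_rate = habitat_transition_rate,
         genes = genes, seed = as.integer(seed)),
    class = "sim_config"
  )
}

n_tips <- function(config) {
  config$n_marine + config$n_freshwater + config$n_brackish
}

#' Simulate the species tree
#'
#' Star topology (independent tips, unit branch lengths) or a Yule
#' pure-birth tree. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(config) {
  n <- n_tips(config)
  if (n < 2) abort("need at least 2 tips")
  tree <- with_local_seed(config$seed + 1L, {
    if (config$tree_model == "star") {
      t <- ape::stree(n, type = "star")
      t$edge.length <- rep(1, nrow(t$edge))
      t
    } else {
      ape::rphylo(n, birth = config$birth_rate, death = 0)
    }
  })
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  tree
}

#' Simulate habitat labels on the tree
#'
#' On a star tree the configured composition is assigned exactly, in a
#' seeded random order. On a Yule tree habitat evolves from a marine root
#' as a symmetric two-state Markov process along branches (flip
#' probability `(1 - exp(-2 q t)) / 2` on a branch of length `t`), after
#' which `n_brackish` random tips are relabelled brackish.
#'
#' @param tree From [simulate_tree()].
#' @param config A [sim_config()].
#' @return Named character vector tip -> habitat, with attribute
#'   `node_states` (marine/freshwater for every node, before brackish
#'   relabelling) for branchwise loss simulation.
#' @export
simulate_habitat <- function(tree, config) {
  n <- length(tree$tip.label)
  with_local_seed(config$seed + 2L, {
    if (config$tree_model == "star") {
      pool <- c(rep("marine", config$n_marine),
                rep("freshwater", config$n_freshwater),
                rep("brackish", config$n_brackish))
      stopifnot(length(pool) == n)
      hab <- sample(pool)
      node_states <- c(ifelse(hab == "freshwater", "freshwater", "marine"),
                       "marine")
    } else {
      q <- config$habitat_transition_rate
      nnode <- tree$Nnode
      states <- character(n + nnode)
      states[n + 1L] <- "marine"
      tr <- ape::reorder.phylo(tree, "postorder")
      for (k in rev(seq_len(nrow(tr$edge)))) {
        parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
        len <- tr$edge.length[[k]]
        p_flip <- (1 - exp(-2 * q * len)) / 2
        flip <- runif(1) < p_flip
        states[child] <- if (flip) {
          setdiff(c("marine", "freshwater"), states[parent])
        } else {
          states[parent]
        }
      }
      hab <- states[seq_len(n)]
      node_states <- states
      if (config$n_brackish > 0) {
        hab[sample(n, config$n_brackish)] <- "brackish"
      }
    }
    structure(setNames(hab, tree$tip.label), node_states = node_states)
  })
}

#' Simulate habitat-dependent gene loss
#'
#' Every gene is present at the root. In `"tip"` mode (the star-tree
#' regime used for the screen's error-rate characterization) each gene is
#' lost independently per tip with the habitat's loss probability;
#' brackish tips use the marine probability. In `"branch"` mode loss
#' happens irreversibly along branches with probability
#' `1 - exp(-rate * length)` per branch, the loss probabilities
#' reinterpreted as per-unit-length rates under the branch's parent
#' habitat — this produces the clade-wide losses a painted tree shows.
#' Genes lost in every species are excluded from the matrix universe with
#' a warning.
#'
#' @param tree From [simulate_tree()].
#' @param habitats From [simulate_habitat()].
#' @param config A [sim_config()].
#' @param mode `"tip"` or `"branch"`.
#' @return A list: `matrix` (a `presence_matrix`) and `truth` (tibble
#'   `gene`, `loss_prob_marine`, `loss_prob_freshwater`,
#'   `planted_effect`).
#' @export
simulate_gene_loss <- function(tree, habitats, config,
                               mode = c("tip", "branch")) {
  mode <- match.arg(mode)
  tips <- tree$tip.label
  genes <- config$genes
  loss_prob_of <- function(hab, g) {
    ifelse(hab == "freshwater", genes$loss_prob_freshwater[[g]],
           genes$loss_prob_marine[[g]])
  }
  pres <- with_local_seed(config$seed + 3L, {
    if (mode == "tip") {
      vapply(seq_len(nrow(genes)), function(g) {
        runif(length(tips)) >= loss_prob_of(habitats[tips], g)
      }, logical(length(tips)))
    } else {
      node_states <- attr(habitats, "node_states")
      n <- length(tips)
      tr <- ape::reorder.phylo(tree, "postorder")
      vapply(seq_len(nrow(genes)), function(g) {
        state <- logical(n + tree$Nnode)
        state[n + 1L] <- TRUE
        for (k in rev(seq_len(nrow(tr$edge)))) {
          parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
          if (!state[parent]) { state[child] <- FALSE; next }
          rate <- loss_prob_of(node_states[parent], g)
          p_loss <- 1 - exp(-rate * tr$edge.length[[k]])
          state[child] <- runif(1) >= p_loss
        }
        state[seq_len(n)]
      }, logical(n))
    }
  })
  colnames(pres) <- genes$symbol
  lost_everywhere <- colSums(pres) == 0
  if (any(lost_everywhere)) {
    warn(paste0("gene(s) absent in every species, dropped from universe: ",
                paste(genes$symbol[lost_everywhere], collapse = ", ")))
  }
  inventories <- tibble(
    species_id = tips,
    genes = purrr::map(seq_along(tips),
                       ~ colnames(pres)[pres[.x, ]])
  )
  mat <- build_matrix(inventories, setNames(as.character(habitats), tips))
  truth <- mutate(genes,
                  planted_effect =
                    .data$loss_prob_marine != .data$loss_prob_freshwater) |>
    rename(gene = "symbol") |>
    filter(!.data$gene %in% genes$symbol[lost_everywhere])
  list(matrix = mat, truth = truth)
}

#' Emit a toy GenBank record for a gene inventory
#'
#' Writes a syntactically valid GenBank flat file containing one CDS per
#' gene (alternating strands), optional tRNA/rRNA features, and random
#' intergenic spacers at a configured GC fraction, such that
#' [read_genbank_record()] followed by [extract_gene_inventory()]
#' recovers the inventory exactly.
#'
#' @param species_id Species identifier (becomes the ORGANISM line).
#' @param genes Character vector of gene symbols.
#' @param seed Integer seed.
#' @param gc Spacer GC fraction (default 0.3, red-algal plastome range).
#' @param cds_length CDS length in bp (multiple of 3).
#' @param n_trna,n_rrna Number of tRNA/rRNA features to add.
#' @param path Optional output path; when given the record is written
#'   there.
#' @return Character vector of GenBank lines (invisibly when `path` is
#'   given).
#' @export
emit_toy_genbank <- function(species_id, genes, seed = 1, gc = 0.3,
                             cds_length = 300, n_trna = 2, n_rrna = 1,
                             path = NULL) {
  if (length(genes) == 0) abort("empty inventory")
  stopifnot(cds_length %% 3 == 0)
  with_local_seed(seed, {
    spacer <- function(len) {
      paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
                   prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
            collapse = "")
    }
    seqs <- character()
    feats <- character()
    pos <- 0L
    add_feature <- function(key, lo, hi, strand, qual, val) {
      loc <- paste0(lo, "..", hi)
      if (strand == "-") loc <- paste0("complement(", loc, ")")
      c(sprintf("     %-16s%s", key, loc),
        sprintf("                     /%s=\"%s\"", qual, val))
    }
    n_rna <- n_trna + n_rrna
    rna_names <- c(if (n_trna) paste0("trn", LETTERS[seq_len(n_trna)]),
                   if (n_rrna) paste0("rrn", c(16, 23, 5)[seq_len(n_rrna)]))
    rna_keys <- c(rep("tRNA", n_trna), rep("rRNA", n_rrna))
    rna_lens <- c(rep(72L, n_trna), rep(120L, n_rrna))
    for (i in seq_along(genes)) {
      sp <- spacer(sample(50:200, 1))
      seqs <- c(seqs, sp); pos <- pos + nchar(sp)
      body <- spacer(cds_length - 6L)
      cds <- paste0("ATG", body, "TAA")
      lo <- pos + 1L; hi <- pos + nchar(cds)
      strand <- if (i %% 2 == 0) "-" else "+"
      feats <- c(feats, add_feature("CDS", lo, hi, strand, "gene",
                                    genes[[i]]))
      seqs <- c(seqs, cds); pos <- hi
    }
    for (j in seq_len(n_rna)) {
      sp <- spacer(sample(50:200, 1))
      seqs <- c(seqs, sp); pos <- pos + nchar(sp)
      rna <- spacer(rna_lens[[j]])
      lo <- pos + 1L; hi <- pos + nchar(rna)
      feats <- c(feats, add_feature(rna_keys[[j]], lo, hi, "+", "gene",
                                    rna_names[[j]]))
      seqs <- c(seqs, rna); pos <- hi
    }
    seqs <- c(seqs, spacer(sample(50:200, 1)))
    full <- paste(seqs, collapse = "")
    n <- nchar(full)

    origin <- character()
    lower <- tolower(full)
    for (start in seq(1, n, by = 60)) {
      chunk <- substring(lower, seq(start, min(start + 59, n), by = 10),
                         pmin(seq(start, min(start + 59, n), by = 10) + 9, n))
      origin <- c(origin, sprintf("%9d %s", start,
                                  paste(chunk, collapse = " ")))
    }
    lines <- c(
      sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-2000",
              gsub("\\s+", "_", species_id), n),
      "DEFINITION  synthetic toy plastid genome (generated fixture).",
      "SOURCE      synthetic",
      paste0("  ORGANISM  ", species_id),
      "FEATURES             Location/Qualifiers",
      sprintf("     %-16s%s", "source", paste0("1..", n)),
      feats,
      "ORIGIN",
      origin,
      "//"
    )
    if (!is.null(path)) {
      writeLines(lines, path)
      return(invisible(lines))
    }
    lines
  })
}

#' Generate a protein with a planted domain architecture
#'
#' Builds a hydrophilic backbone carrying an optional S/T-rich transit
#' prefix, one copy of the packaged heme-oxygenase domain, and `n_tm`
#' poly-leucine 25-mers at recorded positions (the last one placed at the
#' C-terminus when `n_tm > 0`). The returned truth record drives
#' classifier tests: the planted architecture determines the expected
#' isotype by construction.
#'
#' @param n_tm Number of transmembrane segments to plant (>= 0).
#' @param transit Plant an N-terminal transit peptide?
#' @param encoded_in `"plastid"`, `"nucleus"` or `"unknown"`.
#' @param with_domain Include the heme-oxygenase domain copy?
#' @param seed Integer seed.
#' @param seq_id Sequence identifier.
#' @return A list: `record` (tibble `seq_id`, `sequence`, `encoded_in`)
#'   and `truth` (list with `transit`, `tm_starts` 0-based,
#'   `domain_start` 0-based, `expected_isotype`).
#' @export
plant_tm_protein <- function(n_tm, transit = FALSE, encoded_in = "unknown",
                             with_domain = TRUE, seed = 1,
                             seq_id = "planted") {
  if (n_tm < 0) abort("n_tm must be >= 0")
  backbone_aa <- c("R", "K", "D", "E", "N", "Q", "G", "P", "H")
  domain_seq <- read_fasta(system.file("extdata",
                                       "hemeo_domain_synthetic.fasta",
                                       package = "plastome"))$sequence[[1]]
  with_local_seed(seed, {
    backbone <- function(len) {
      paste(sample(backbone_aa, len, replace = TRUE), collapse = "")
    }
    parts <- character(); lens <- integer()
    push <- function(s) {
      parts[[length(parts) + 1]] <<- s
      lens[[length(lens) + 1]] <<- nchar(s)
    }
    if (transit) {
      push(paste0("MA", paste(sample(c("S", "T", "A"), 38, replace = TRUE,
                                     prob = c(0.6, 0.3, 0.1)),
                              collapse = "")))
    } else {
      push(paste0("M", backbone(39)))
    }
    push(backbone(30))
    domain_start <- NA_integer_
    if (with_domain) {
      domain_start <- sum(lens)
      push(domain_seq)
    }
    push(backbone(40))
    tm_starts <- integer()
    if (n_tm > 0) {
      for (i in seq_len(n_tm)) {
        tm_starts <- c(tm_starts, sum(lens))
        push(strrep("L", 25))
        if (i < n_tm) push(backbone(40))
      }
      push(backbone(15))
    } else {
      push(backbone(25))
    }
    seq <- paste(parts, collapse = "")
    expected <- if (!with_domain) {
      "unclassified"
    } else if (transit && n_tm == 0) {
      "HMOX1"
    } else if (n_tm > 0 && transit) {
      "pbsA"
    } else if (encoded_in == "plastid" && n_tm > 0) {
      "pbsA"
    } else if (encoded_in == "nucleus" && n_tm > 0) {
      "HMOX2"
    } else {
      "unclassified"
    }
    list(
      record = tibble(seq_id = seq_id, sequence = seq,
                      encoded_in = encoded_in),
      truth = list(transit = transit, tm_starts = tm_starts,
                   domain_start = domain_start,
                   expected_isotype = expected)
    )
  })
}

#' Generate a toy clustered hit table
#'
#' Builds `n_clusters` groups of sequences with strong within-cluster
#' hits (passing every network threshold) and weak between-cluster hits
#' planted below threshold, so the expected component structure is known
#' by construction.
#'
#' @param n_clusters Number of clusters.
#' @param cluster_size Sequences per cluster.
#' @param seq_length Sequence length used for every node.
#' @param seed Integer seed.
#' @return A list: `hits` (tibble in outfmt-6 column layout), `lengths`
#'   (named vector), `truth` (named vector seq_id -> cluster).
#' @export
simulate_hit_table <- function(n_clusters = 3, cluster_size = 4,
                               seq_length = 100, seed = 1) {
  with_local_seed(seed, {
    ids <- unlist(purrr::map(seq_len(n_clusters), function(k) {
      sprintf("c%d_s%d", k, seq_len(cluster_size))
    }))
    cluster <- rep(seq_len(n_clusters), each = cluster_size)
    lengths <- setNames(rep(seq_length, length(ids)), ids)
    mk_hit <- function(q, s, pid, alen, ev) {
      tibble(query_id = q, subject_id = s, percent_identity = pid,
             align_length = as.integer(alen), mismatches = 0L,
             gap_opens = 0L, q_start = 1L, q_end = as.integer(alen),
             s_start = 1L, s_end = as.integer(alen), e_value = ev,
             bit_score = 200)
    }
    hits <- list()
    for (k in seq_len(n_clusters)) {
      members <- ids[cluster == k]
      pairs <- utils::combn(members, 2)
      for (j in seq_len(ncol(pairs))) {
        hits[[length(hits) + 1]] <-
          mk_hit(pairs[1, j], pairs[2, j], pid = runif(1, 60, 95),
                 alen = seq_length, ev = 10^runif(1, -60, -20))
      }
    }
    # planted sub-threshold between-cluster hits: fail e-value or identity
    inter <- utils::combn(seq_len(n_clusters), 2)
    for (j in seq_len(ncol(inter))) {
      a <- ids[cluster == inter[1, j]][1]
      b <- ids[cluster == inter[2, j]][1]
      fail_on <- if (j %% 2 == 0) "identity" else "evalue"
      hits[[length(hits) + 1]] <- if (fail_on == "identity") {
        mk_hit(a, b, pid = 15, alen = seq_length, ev = 1e-20)
      } else {
        mk_hit(a, b, pid = 50, alen = seq_length, ev = 1e-3)
      }
    }
    list(hits = bind_rows(hits), lengths = lengths,
         truth = setNames(cluster, ids))
  })
}

#' Write a complete synthetic input bundle
#'
#' Simulates the full stated world — tree, habitats, presence matrix,
#' three toy GenBank records, planted-architecture proteins, a clustered
#' hit table — and writes everything to `out_dir` in the plain-text
#' formats the pipeline reads, plus `truth.json` recording every planted
#' parameter.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written plus the
#'   simulated objects (`tree`, `habitats`, `matrix`, `truth`).
#' @export
simulate_bundle <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  tree <- simulate_tree(config)
  habitats <- simulate_habitat(tree, config)
  loss <- simulate_gene_loss(tree, habitats, config)
  ape::write.tree(tree, p("tree.nwk"))
  readr::write_tsv(tibble(species_id = names(habitats),
                          habitat = as.character(habitats)),
                   p("habitat.tsv"))
  write_matrix(loss$matrix, p("matrix.tsv"))

  gb_paths <- character()
  for (i in seq_len(min(3, nrow(loss$matrix)))) {
    sp <- loss$matrix$species_id[[i]]
    genes <- matrix_genes(loss$matrix)[unlist(loss$matrix[i, matrix_genes(loss$matrix)])]
    f <- p(paste0(sp, ".gb"))
    emit_toy_genbank(sp, genes, seed = config$seed + 100L + i, path = f)
    gb_paths <- c(gb_paths, f)
  }

  plants <- list(
    plant_tm_protein(0, transit = TRUE, encoded_in = "nucleus",
                     seed = config$seed + 11L, seq_id = "prot_hmox1"),
    plant_tm_protein(2, transit = FALSE, encoded_in = "nucleus",
                     seed = config$seed + 12L, seq_id = "prot_hmox2"),
    plant_tm_protein(1, transit = FALSE, encoded_in = "plastid",
                     seed = config$seed + 13L, seq_id = "prot_pbsa")
  )
  prots <- bind_rows(purrr::map(plants, "record"))
  write_fasta(mutate(prots, seq_id = paste0(.data$seq_id, " encoded_in=",
                                            .data$encoded_in)),
              p("proteins.faa"))

  hitsim <- simulate_hit_table(seed = config$seed + 21L)
  readr::write_tsv(hitsim$hits, p("hits.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(seq_id = names(hitsim$lengths),
                          length = unname(hitsim$lengths)),
                   p("lengths.tsv"))

  truth <- list(
    seed = config$seed,
    genes = loss$truth,
    habitat_composition = as.list(table(as.character(habitats))),
    planted_isotypes = as.list(setNames(
      purrr::map_chr(plants, ~ .x$truth$expected_isotype),
      purrr::map_chr(plants, ~ .x$record$seq_id))),
    hit_clusters = as.list(hitsim$truth)
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(
    paths = list(tree = p("tree.nwk"), habitat = p("habitat.tsv"),
                 matrix = p("matrix.tsv"), genbank = gb_paths,
                 proteins = p("proteins.faa"), hits = p("hits.tsv"),
                 lengths = p("lengths.tsv"), truth = p("truth.json")),
    tree = tree, habitats = habitats, matrix = loss$matrix,
    truth = truth
  ))
}
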