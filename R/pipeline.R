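#' Assemble and validate a pipeline run configuration
#'
#' A declarative run description: input paths, screen parameters, protein
#' parameters, network thresholds and the output directory. Defaults
#' reproduce the survey's stated settings (alpha 0.01, brackish excluded,
#' plain Pearson chi-square, no multiple-testing adjustment, network
#' thresholds 1e-05 / 20% / 70%). All parameters are validated before
#' any stage runs; validation errors name the offending field.
#'
#' @param matrix Path to a presence-matrix TSV (see [write_matrix()]),
#'   *or* `genbank` + `habitat` below.
#' @param genbank Character vector of GenBank flat-file paths (used with
#'   `habitat` when `matrix` is absent).
#' @param habitat Path to a species/habitat TSV.
#' @param tree Path to a rooted Newick tree (optional stage).
#' @param proteins Path to a protein FASTA (optional stage).
#' @param hits,lengths Paths to a hit table and a seq_id/length TSV
#'   (optional stage).
#' @param out_dir Output directory.
#' @param alpha,brackish_policy,correction,adjust Screen parameters, see
#'   [screen_genes()].
#' @param genes Genes to map on the tree; defaults to the significant
#'   genes of the screen.
#' @param thresholds Network thresholds, see [network_thresholds()].
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(matrix = NULL, genbank = NULL, habitat = NULL,
                       tree = NULL, proteins = NULL, hits = NULL,
                       lengths = NULL, out_dir = "plastome_out",
                       alpha = 0.01,
                       brackish_policy = "exclude", correction = FALSE,
                       adjust = "none", genes = NULL,
                       thresholds = network_thresholds(), seed = 1) {
  need <- function(path, what) {
    if (!is.null(path) && !all(file.exists(path))) {
      abort(paste0("config validation: ", what, " file(s) not found: ",
                   paste(path[!file.exists(path)], collapse = ", ")))
    }
  }
  if (is.null(matrix) && is.null(genbank)) {
    abort("config validation: need either 'matrix' or 'genbank' input")
  }
  if (!is.null(genbank) && is.null(matrix) && is.null(habitat)) {
    abort("config validation: 'genbank' input requires a 'habitat' table")
  }
  need(matrix, "matrix"); need(genbank, "genbank"); need(habitat, "habitat")
  need(tree, "tree"); need(proteins, "proteins"); need(hits, "hits")
  need(lengths, "lengths")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    abort("config validation: alpha must be in (0, 1]")
  }
  brackish_policy <- match.arg(brackish_policy,
                               c("exclude", "as_marine", "as_freshwater"))
  adjust <- match.arg(adjust, c("none", "bonferroni", "BH"))
  structure(
    list(matrix = matrix, genbank = genbank, habitat = habitat,
         tree = tree, proteins = proteins, hits = hits, lengths = lengths,
         out_dir = out_dir, alpha = alpha,
         brackish_policy = brackish_policy, correction = correction,
         adjust = adjust, genes = genes, thresholds = thresholds,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' @param path Path to a JSON file whose fields are [run_config()]
#'   arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- do.call(network_thresholds, as.list(raw$thresholds))
  }
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full comparative analysis
#'
#' Orchestrates inventory extraction, matrix assembly, the habitat
#' association screen, parsimony mapping on the tree, isotype
#' classification and the similarity network — whichever stages the
#' config provides inputs for — and writes `assoc.tsv`, `phylomap.tsv`,
#' `isotypes.tsv`, `net.graphml`, `summary.md` and a machine-readable
#' `manifest.json` (package version, parameters, input checksums) to the
#' output directory. Identical inputs and config produce identical
#' outputs, manifest timestamp aside.
#'
#' @param config A [run_config()] (or a JSON path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory stage results: `matrix`,
#'   `screen`, `phylomap`, `isotypes`, `network`, `paths`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  paths <- list()

  mat <- stage("matrix", {
    if (!is.null(config$matrix)) {
      read_matrix(config$matrix)
    } else {
      hab <- readr::read_tsv(config$habitat,
                             col_types = readr::cols(.default = "c"))
      inventories <- bind_rows(purrr::map(config$genbank, function(f) {
        extract_gene_inventory(read_genbank_record(f))
      }))
      build_matrix(inventories, hab)
    }
  })

  screen <- stage("association", {
    screen_genes(mat, alpha = config$alpha,
                 brackish_policy = config$brackish_policy,
                 correction = config$correction, adjust = config$adjust)
  })
  readr::write_tsv(as_tibble(screen), p("assoc.tsv"))
  paths$assoc <- p("assoc.tsv")

  phylomap <- NULL
  if (!is.null(config$tree)) {
    phylomap <- stage("phylo_mapping", {
      tree <- read_newick(config$tree)
      missing <- setdiff(mat$species_id, tree$tip.label)
      if (length(missing)) {
        abort(paste0("matrix species missing from tree: ",
                     paste(missing, collapse = ", ")))
      }
      genes <- config$genes %||% screen$gene[screen$significant]
      if (length(genes) == 0) genes <- matrix_genes(mat)
      map_genes(tree, mat, genes)
    })
    readr::write_tsv(phylomap, p("phylomap.tsv"))
    paths$phylomap <- p("phylomap.tsv")
  }

  isotypes <- NULL
  if (!is.null(config$proteins)) {
    isotypes <- stage("protein_features", {
      classify_proteins(config$proteins)
    })
    readr::write_tsv(isotypes, p("isotypes.tsv"))
    paths$isotypes <- p("isotypes.tsv")
  }

  network <- NULL
  if (!is.null(config$hits) && !is.null(config$lengths)) {
    network <- stage("similarity_network", {
      hits <- read_hits_tabular(config$hits)
      lens <- readr::read_tsv(config$lengths,
                              col_types = readr::cols(seq_id = "c",
                                                      length = "i"))
      build_network(hits, lens, config$thresholds)
    })
    write_network_graphml(network, p("net.graphml"))
    write_network_edges(network, p("net_edges.tsv"))
    paths$network <- p("net.graphml")
  }

  sig <- filter(as_tibble(screen), .data$significant)
  summary_lines <- c(
    "# Habitat-association screen summary", "",
    sprintf("- genes screened: %d", nrow(screen)),
    sprintf("- significant at alpha = %g (%s, %s): %d",
            config$alpha, config$brackish_policy,
            if (config$correction) "Yates-corrected" else "uncorrected",
            nrow(sig)),
    "",
    "| gene | concordance | direction | chi2 | p |",
    "|------|-------------|-----------|------|---|",
    sprintf("| %s | %.3f | %s | %.2f | %.3g |", sig$gene, sig$concordance,
            sig$direction, sig$chi2, sig$p_value)
  )
  writeLines(summary_lines, p("summary.md"))
  paths$summary <- p("summary.md")

  inputs <- purrr::compact(config[c("matrix", "genbank", "habitat", "tree",
                                    "proteins", "hits", "lengths")])
  manifest <- list(
    package = "plastome",
    version = as.character(utils::packageVersion("plastome")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    parameters = list(alpha = config$alpha,
                      brackish_policy = config$brackish_policy,
                      correction = config$correction,
                      adjust = config$adjust,
                      thresholds = config$thresholds),
    inputs = purrr::map(inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- p("manifest.json")

  invisible(list(matrix = mat, screen = screen, phylomap = phylomap,
                 isotypes = isotypes, network = network, paths = paths))
}
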