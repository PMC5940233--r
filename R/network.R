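#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Standard 12-column layout: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' e-value, bit score. Malformed lines (short, or non-numeric where a
#' number is required) are collected into an `errors` attribute rather
#' than aborting; an empty file yields an empty tibble.
#'
#' @param path Path to a tab/whitespace-delimited hit file.
#' @return A tibble of typed hits with attribute `errors` (character
#'   vector of rejected lines, possibly empty).
#' @export
read_hits_tabular <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  empty <- as_tibble(setNames(
    list(character(), character(), numeric(), integer(), integer(),
         integer(), integer(), integer(), integer(), integer(), numeric(),
         numeric()), cols))
  if (length(lines) == 0) return(structure(empty, errors = character()))
  parsed <- purrr::map(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 12) return(NULL)
    nums <- suppressWarnings(as.numeric(f[3:12]))
    if (any(is.na(nums))) return(NULL)
    tibble(query_id = f[[1]], subject_id = f[[2]],
           percent_identity = nums[[1]], align_length = as.integer(nums[[2]]),
           mismatches = as.integer(nums[[3]]), gap_opens = as.integer(nums[[4]]),
           q_start = as.integer(nums[[5]]), q_end = as.integer(nums[[6]]),
           s_start = as.integer(nums[[7]]), s_end = as.integer(nums[[8]]),
           e_value = nums[[9]], bit_score = nums[[10]])
  })
  ok <- !purrr::map_lgl(parsed, is.null)
  out <- if (any(ok)) bind_rows(parsed[ok]) else empty
  structure(out, errors = lines[!ok])
}

#' Default EGN-style network thresholds
#'
#' The connection thresholds used for the heme-oxygenase gene network:
#' e-value at most 1e-05, identity at least 20%, alignment covering at
#' least 20% of the shorter sequence and at least 70% of *both*
#' sequences. The two coverage clauses are applied conjunctively (the 20%
#' clause is then redundant but kept for fidelity to the stated settings).
#'
#' @param e_value,identity,min_short_coverage,both_coverage Override any
#'   threshold.
#' @return A named list of thresholds.
#' @export
network_thresholds <- function(e_value = 1e-5, identity = 20,
                               min_short_coverage = 0.20,
                               both_coverage = 0.70) {
  list(e_value = e_value, identity = identity,
       min_short_coverage = min_short_coverage,
       both_coverage = both_coverage)
}

#' Filter pairwise hits into network edges
#'
#' Applies the similarity-network thresholds to a hit table: a hit
#' survives iff its e-value, identity and the coverage of both sequences
#' (alignment length over sequence length, gaps not subtracted) all pass.
#' Self-hits are removed and reciprocal duplicates collapse to one edge,
#' keeping the lowest-e-value supporting hit. Filtering is idempotent.
#'
#' @param hits Tibble from [read_hits_tabular()].
#' @param lengths Named integer vector (seq_id -> sequence length) or
#'   tibble with `seq_id`, `length`.
#' @param thresholds A [network_thresholds()] list.
#' @return Edge tibble: `from`, `to` (sorted within pair), plus the
#'   supporting hit's `percent_identity`, `align_length`, `e_value`,
#'   `bit_score`.
#' @export
filter_hits <- function(hits, lengths, thresholds = network_thresholds()) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$seq_id)
  }
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     names(lengths))
  if (length(unknown)) {
    abort(paste0("hits reference sequences with unknown length: ",
                 paste(unknown, collapse = ", ")))
  }
  lq <- unname(lengths[hits$query_id])
  ls <- unname(lengths[hits$subject_id])
  keep <- hits$query_id != hits$subject_id &
    hits$e_value <= thresholds$e_value &
    hits$percent_identity >= thresholds$identity &
    hits$align_length >= thresholds$min_short_coverage * pmin(lq, ls) &
    hits$align_length >= thresholds$both_coverage * lq &
    hits$align_length >= thresholds$both_coverage * ls
  surv <- hits[keep, , drop = FALSE]
  if (nrow(surv) == 0) {
    return(tibble(from = character(), to = character(),
                  percent_identity = numeric(), align_length = integer(),
                  e_value = numeric(), bit_score = numeric()))
  }
  surv |>
    mutate(from = pmin(.data$query_id, .data$subject_id),
           to = pmax(.data$query_id, .data$subject_id)) |>
    arrange(.data$e_value, dplyr::desc(.data$bit_score)) |>
    distinct(.data$from, .data$to, .keep_all = TRUE) |>
    select("from", "to", "percent_identity", "align_length", "e_value",
           "bit_score") |>
    arrange(.data$from, .data$to)
}

#' Build the gene similarity network
#'
#' Nodes are *all* sequences in the lengths table — sequences with no
#' surviving hit appear as singletons, so cluster censuses cover the
#' whole input — and edges are the filtered hits.
#'
#' @inheritParams filter_hits
#' @return A `gene_network`: list with `graph` (igraph), `edges` (the
#'   [filter_hits()] tibble), `nodes` (character vector).
#' @export
build_network <- function(hits, lengths, thresholds = network_thresholds()) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$seq_id)
  }
  edges <- filter_hits(hits, lengths, thresholds)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = names(lengths))
  structure(list(graph = g, edges = edges, nodes = names(lengths)),
            class = "gene_network")
}

#' Connected components of a gene network
#'
#' @param network A `gene_network`.
#' @return A list of character vectors (node sets), singletons included,
#'   sorted by decreasing size; members sorted within each component.
#' @export
connected_components <- function(network) {
  comp <- igraph::components(network$graph)
  sets <- split(names(comp$membership), comp$membership)
  sets <- purrr::map(sets, sort)
  unname(sets[order(-purrr::map_int(sets, length))])
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", igraph::components(x$graph)$no, " components\n", sep = "")
  invisible(x)
}

#' Write a gene network
#'
#' `write_network_graphml()` writes GraphML (via igraph);
#' `write_network_edges()` writes the edge list as TSV.
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(network, path) {
  readr::write_tsv(network$edges, path)
  invisible(path)
}
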