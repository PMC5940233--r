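#' Assemble a species-by-gene presence/absence matrix with habitat labels
#'
#' Builds the survey table the habitat screen runs on: one row per species,
#' a `habitat` column (marine / freshwater / brackish) and one logical
#' column per gene. The gene universe is the union of all inventories'
#' gene sets, sorted; presence is binary (copy number ignored). A gene
#' unannotated in a record counts as absent — no imputation.
#'
#' @param inventories Tibble with `species_id` and a `genes` list-column
#'   (as from [extract_gene_inventory()] rows bound together), or a named
#'   list of character vectors keyed by species id.
#' @param habitat Either a named character vector (species id -> habitat)
#'   or a data frame with columns `species_id` and `habitat`. Values are
#'   matched case-insensitively against marine / freshwater / brackish;
#'   anything else is an error.
#' @return A `presence_matrix`: tibble with columns `species_id`,
#'   `habitat`, then one logical column per gene.
#' @export
build_matrix <- function(inventories, habitat) {
  if (is.list(inventories) && !is.data.frame(inventories)) {
    inventories <- tibble(species_id = names(inventories),
                          genes = unname(inventories))
  }
  if (anyDuplicated(inventories$species_id)) {
    abort("duplicate species ids in inventories")
  }
  hab <- normalize_habitat(habitat)
  missing <- setdiff(inventories$species_id, names(hab))
  if (length(missing)) {
    abort(paste0("species missing habitat labels: ",
                 paste(missing, collapse = ", ")))
  }
  universe <- sort(unique(unlist(inventories$genes)))
  if (length(universe) == 0) abort("empty gene universe")
  pres <- purrr::map(inventories$genes, ~ universe %in% .x)
  mat <- do.call(rbind, pres)
  colnames(mat) <- universe
  out <- dplyr::bind_cols(
    tibble(species_id = inventories$species_id,
           habitat = unname(hab[inventories$species_id])),
    as_tibble(mat)
  )
  new_presence_matrix(out)
}

new_presence_matrix <- function(x) {
  class(x) <- c("presence_matrix", class(tibble()))
  x
}

normalize_habitat <- function(habitat) {
  if (is.data.frame(habitat)) {
    hab <- setNames(habitat$habitat, habitat$species_id)
  } else {
    hab <- habitat
  }
  val <- tolower(trimws(hab))
  bad <- !val %in% c("marine", "freshwater", "brackish")
  if (any(bad)) {
    abort(paste0("unknown habitat value(s): ",
                 paste(unique(hab[bad]), collapse = ", "),
                 " (for ", paste(names(hab)[bad], collapse = ", "), ")"))
  }
  setNames(val, names(hab))
}

#' Gene columns of a presence matrix
#' @param matrix A `presence_matrix`.
#' @return Character vector of gene symbols (column names).
#' @export
matrix_genes <- function(matrix) {
  setdiff(names(matrix), c("species_id", "habitat"))
}

#' Group-exclusive and shared gene sets (Venn logic)
#'
#' For two disjoint species groups, reports the genes found in every
#' member of one group and no member of the other — the sets a Venn
#' diagram of strict gene contents displays — plus the genes present in
#' every species of both groups.
#'
#' @param matrix A `presence_matrix`.
#' @param group_a,group_b Disjoint character vectors of species ids, both
#'   subsets of the matrix species.
#' @return A list with `only_in_all_of_a`, `only_in_all_of_b`, `shared`
#'   (character vectors of gene symbols).
#' @export
unique_gene_sets <- function(matrix, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) abort("empty group")
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint")
  unknown <- setdiff(c(group_a, group_b), matrix$species_id)
  if (length(unknown)) {
    abort(paste0("species not in matrix: ", paste(unknown, collapse = ", ")))
  }
  genes <- matrix_genes(matrix)
  sub <- function(ids) as.matrix(matrix[match(ids, matrix$species_id), genes,
                                        drop = FALSE])
  a <- sub(group_a); b <- sub(group_b)
  all_a <- apply(a, 2, all); any_a <- apply(a, 2, any)
  all_b <- apply(b, 2, all); any_b <- apply(b, 2, any)
  list(
    only_in_all_of_a = genes[all_a & !any_b],
    only_in_all_of_b = genes[all_b & !any_a],
    shared = genes[all_a & all_b]
  )
}

#' Write / read a presence matrix as TSV
#'
#' Columns `species_id`, `habitat`, then one 0/1 column per gene.
#' `read_matrix()` inverts `write_matrix()`; habitat values are validated
#' case-insensitively on read and anything outside
#' marine/freshwater/brackish is an error naming the offending row.
#'
#' @param matrix A `presence_matrix`.
#' @param path File path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns a `presence_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  genes <- matrix_genes(matrix)
  flat <- mutate(matrix, across(dplyr::all_of(genes), as.integer))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    species_id = "c", habitat = "c", .default = "i"
  ))
  hab <- normalize_habitat(setNames(flat$habitat, flat$species_id))
  genes <- setdiff(names(flat), c("species_id", "habitat"))
  out <- mutate(flat,
                habitat = unname(hab[flat$species_id]),
                across(dplyr::all_of(genes), as.logical))
  new_presence_matrix(out)
}

#' @export
print.presence_matrix <- function(x, ...) {
  genes <- matrix_genes(x)
  cat("<presence_matrix> ", nrow(x), " species x ", length(genes), " genes (",
      paste(names(table(x$habitat)), table(x$habitat),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Heatmap of a presence/absence matrix
#'
#' Tiles species (rows, grouped by habitat) by genes (columns); filled
#' tiles mark presence.
#'
#' @param object A `presence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.presence_matrix <- function(object, ...) {
  genes <- matrix_genes(object)
  long <- tidyr::pivot_longer(object, dplyr::all_of(genes),
                              names_to = "gene", values_to = "present")
  ord <- arrange(object, .data$habitat, .data$species_id)$species_id
  long$species_id <- factor(long$species_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$species_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "white")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$habitat),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
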