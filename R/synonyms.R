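#' Packaged gene-symbol synonym table
#'
#' Depositors of plastid genome records are inconsistent in gene naming:
#' case varies ("PbsA", "pbsa"), ycf numbers get zero-padded ("ycf034"),
#' and some records carry only a `/product` qualifier ("heme oxygenase").
#' This table maps lower-cased raw names and common product descriptions to
#' canonical plastid gene symbols so inventories are comparable across
#' depositors. Canonical symbols follow the standard mixed-case convention
#' (psbA, rbcL, ycf34) and are fixed points of [normalize_gene_symbol()].
#'
#' @return A tibble with columns `raw` (lower-cased lookup key) and
#'   `canonical`.
#' @export
default_synonym_table <- function() {
  canon <- c(
    # photosystem / phycobilisome / photosynthesis
    paste0("psa", c("A", "B", "C", "D", "E", "F", "I", "J", "K", "L", "M")),
    paste0("psb", c("A", "B", "C", "D", "E", "F", "H", "I", "J", "K", "L",
                    "N", "T", "V", "W", "X", "Y", "Z")),
    paste0("pet", c("A", "B", "D", "F", "G", "J", "L", "M", "N")),
    paste0("atp", c("A", "B", "D", "E", "F", "G", "H", "I")),
    paste0("apc", c("A", "B", "D", "E", "F")),
    paste0("cpc", c("A", "B", "G")), paste0("cpe", c("A", "B")),
    "rbcL", "rbcS", "pbsA",
    # gene expression
    paste0("rpl", c(1:6, 9, 11:14, 16, 18:24, 27:29, 31:36)),
    paste0("rps", c(1:14, 16:20)),
    paste0("rpo", c("A", "B", "C1", "C2", "Z")),
    "tufA", "infB", "infC", "secA", "secG", "secY", "tatC", "ftsH",
    "clpC", "dnaB", "dnaK", "groEL", "grx", "trxA",
    # chlorophyll / cofactor biosynthesis and misc
    paste0("chl", c("B", "I", "L", "N")),
    "hemA", "thiG", "thiS", "ilvB", "ilvH", "accA", "accB", "accD",
    "acpP", "fabH", "carA", "gltB", "glnB", "odpA", "odpB", "pgmA",
    "moeB", "preA", "ccs1", "ccsA", "cemA", "cbbX", "ompR", "ntcA",
    "nblA", "syfB", "syh", "bas1", "trpA", "trpG", "dsbD", "rnl", "rne",
    # conserved hypothetical ORFs seen in red algal plastomes
    paste0("ycf", c(1:4, 12, 17, 19:24, 26:27, 29:39, 41, 43, 45:46,
                    52:55, 57, 59:61, 63, 65, 80, 85, 86, 88:91))
  )
  self <- tibble(raw = tolower(canon), canonical = canon)
  products <- tibble(
    raw = c(
      "heme oxygenase", "haem oxygenase",
      "glutaredoxin",
      "ribulose-1,5-bisphosphate carboxylase/oxygenase large subunit",
      "ribulose 1,5-bisphosphate carboxylase large subunit",
      "photosystem ii protein d1", "photosystem ii d1 protein",
      "photosystem i p700 chlorophyll a apoprotein a1",
      "elongation factor tu", "cell division protein ftsh"
    ),
    canonical = c("pbsA", "pbsA", "grx", "rbcL", "rbcL", "psbA", "psbA",
                  "psaA", "tufA", "ftsH")
  )
  distinct(bind_rows(self, products), .data$raw, .keep_all = TRUE)
}

#' Read a synonym table from TSV
#'
#' Two columns, `raw` and `canonical`; `raw` keys are lower-cased on read.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `raw`, `canonical`.
#' @export
read_synonym_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("raw", "canonical") %in% names(tab))) {
    abort("synonym table needs columns 'raw' and 'canonical'")
  }
  mutate(tab, raw = tolower(.data$raw))
}

#' Normalize a raw gene name to a canonical symbol
#'
#' Normalization: strip whitespace; remove zero padding in numbered ORF
#' names (ycf034 -> ycf34); strip trailing locus suffixes (`_1`, `-2`,
#' `.1`); then look the lower-cased key up in the synonym table. Names not
#' in the table are returned lower-cased, which makes the function
#' idempotent: `normalize(normalize(x)) == normalize(x)`.
#'
#' @param raw Character vector of raw gene names (vectorized).
#' @param table Synonym table as from [default_synonym_table()].
#' @return Character vector of canonical symbols.
#' @export
normalize_gene_symbol <- function(raw, table = default_synonym_table()) {
  raw <- trimws(raw)
  if (any(!nzchar(raw))) abort("empty gene name cannot be normalized")
  x <- sub("[._-][0-9]+$", "", raw)
  x <- sub("^([A-Za-z]+?)0+([1-9][0-9]*)$", "\\1\\2", x)
  key <- tolower(x)
  hit <- match(key, table$raw)
  ifelse(is.na(hit), key, table$canonical[hit])
}

#' Extract a normalized gene inventory from an annotated genome
#'
#' The gene set is the normalized names of CDS features (gene qualifier
#' preferred, product-qualifier synonym lookup as fallback); duplicate gene
#' copies collapse to one set member. CDS features with neither qualifier
#' are skipped. Summary statistics come from [genome_summary()].
#'
#' @param genome An `annotated_genome`.
#' @param table Synonym table.
#' @return A one-row tibble: `species_id`, `genes` (list-column of sorted
#'   canonical symbols), `n_genes`, then the [genome_summary()] columns.
#' @export
extract_gene_inventory <- function(genome, table = default_synonym_table()) {
  stopifnot(inherits(genome, "annotated_genome"))
  cds <- filter(genome$features, .data$kind == "CDS")
  raw <- ifelse(nzchar(cds$gene), cds$gene, cds$product)
  raw <- raw[nzchar(raw)]
  genes <- if (length(raw)) sort(unique(normalize_gene_symbol(raw, table))) else character()
  stats <- genome_summary(genome)
  n_genes <- length(genes)
  tibble(
    species_id = genome$species_id,
    genes = list(genes),
    n_genes = n_genes
  ) |>
    dplyr::bind_cols(select(stats, -"species_id"))
}

#' Write / read gene inventories as TSV
#'
#' One row per species; the gene list is serialized as a comma-separated
#' string in the `genes` column. `read_inventories()` inverts
#' `write_inventories()` exactly.
#'
#' @param inventories Tibble as returned by [extract_gene_inventory()]
#'   (rows may be bound across species).
#' @param path Output path.
#' @return `write_inventories()` returns `path` invisibly;
#'   `read_inventories()` returns the inventories tibble.
#' @export
write_inventories <- function(inventories, path) {
  flat <- mutate(inventories,
                 genes = purrr::map_chr(.data$genes, paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_inventories
#' @export
read_inventories <- function(path) {
  flat <- readr::read_tsv(path, col_types = readr::cols(
    species_id = "c", genes = "c", .default = "d"
  ))
  mutate(flat,
         genes = purrr::map(.data$genes, ~ strsplit(.x, ",")[[1]]),
         dplyr::across(dplyr::starts_with("n_"), as.integer),
         total_bp = as.integer(.data$total_bp))
}
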