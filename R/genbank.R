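#' Read an annotated plastid genome from a GenBank flat file
#'
#' Parses a GenBank flat file (LOCUS/FEATURES/ORIGIN) into an
#' `annotated_genome` object holding the uppercase nucleotide sequence and a
#' feature table. Only feature kinds relevant to gene-content analysis are
#' kept typed (`CDS`, `tRNA`, `rRNA`, `intron`); everything except `source`
#' is retained as `other`. GenBank 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention at this boundary.
#'
#' Joined / trans-spliced locations (`join(...)`, `order(...)`) are treated
#' as a single feature spanning the union of their parts, since only gene
#' presence/absence matters downstream. Features lacking both a `/gene` and
#' a `/product` qualifier are kept with an empty `gene` and a warning.
#'
#' @param path Path to a GenBank flat file.
#' @param species_id Species identifier to attach; defaults to the ORGANISM
#'   line if present, else the LOCUS name.
#' @return An object of class `annotated_genome`: a list with `species_id`,
#'   `sequence` (single uppercase string) and `features`, a tibble with
#'   columns `kind`, `gene` (raw name, gene qualifier preferred),
#'   `product`, `start`, `end` (0-based half-open span) and `strand`.
#' @export
read_genbank_record <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0) {
    abort(paste0("no ORIGIN block in ", path, ": cannot read sequence"))
  }
  origin_at <- origin_at[[1]]
  seq_lines <- lines[seq(origin_at + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) {
    abort(paste0("empty sequence in ", path))
  }

  if (is.null(species_id)) {
    org <- grep("^\\s{2}ORGANISM\\s+", lines, value = TRUE)
    if (length(org) > 0) {
      species_id <- sub("^\\s{2}ORGANISM\\s+", "", org[[1]])
    } else {
      locus <- grep("^LOCUS", lines, value = TRUE)
      species_id <- if (length(locus)) strsplit(locus[[1]], "\\s+")[[1]][2] else "unknown"
    }
  }

  feat_at <- grep("^FEATURES", lines)
  features <- empty_feature_table()
  if (length(feat_at) > 0) {
    block <- lines[seq(feat_at[[1]] + 1L, origin_at - 1L)]
    features <- parse_feature_block(block, nchar(sequence))
  }

  structure(
    list(species_id = species_id, sequence = sequence, features = features),
    class = "annotated_genome"
  )
}

empty_feature_table <- function() {
  tibble(
    kind = character(), gene = character(), product = character(),
    start = integer(), end = integer(), strand = character()
  )
}

# GenBank feature keys start at column 6; qualifier/continuation lines are
# indented further. Locations may continue across lines before the first
# qualifier.
parse_feature_block <- function(block, seq_len) {
  key_line <- grepl("^\\s{5}\\S", block)
  idx <- which(key_line)
  if (length(idx) == 0) return(empty_feature_table())
  ends <- c(idx[-1] - 1L, length(block))

  rows <- purrr::map2(idx, ends, function(i, j) {
    chunk <- block[i:j]
    first <- strsplit(trimws(chunk[[1]]), "\\s+")[[1]]
    key <- first[[1]]
    if (identical(key, "source")) return(NULL)
    loc <- paste(first[-1], collapse = "")
    k <- 2L
    while (k <= length(chunk) && !grepl("^\\s+/", chunk[[k]])) {
      loc <- paste0(loc, trimws(chunk[[k]]))
      k <- k + 1L
    }
    quals <- parse_qualifiers(chunk[seq_len(length(chunk)) >= k])
    parsed <- parse_location(loc)
    kind <- if (key %in% c("CDS", "tRNA", "rRNA", "intron")) key else "other"
    gene <- quals[["gene"]] %||% ""
    product <- quals[["product"]] %||% ""
    if (kind != "other" && !nzchar(gene) && !nzchar(product)) {
      warn(paste0(kind, " feature at ", loc, " has no gene or product qualifier"))
    }
    tibble(
      kind = kind, gene = gene, product = product,
      start = parsed$start, end = parsed$end, strand = parsed$strand
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0 && any(out$start < 0 | out$end > seq_len)) {
    abort("feature coordinates outside the sequence")
  }
  out
}

parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  txt <- paste(trimws(lines), collapse = " ")
  starts <- gregexpr("/[A-Za-z_]+=", txt)[[1]]
  if (starts[[1]] == -1) return(list())
  pieces <- substring(txt, starts, c(starts[-1] - 1L, nchar(txt)))
  out <- list()
  for (p in pieces) {
    m <- regmatches(p, regexec("^/([A-Za-z_]+)=\"?([^\"]*)\"?\\s*$", p))[[1]]
    if (length(m) == 3) out[[m[[2]]]] <- trimws(m[[3]])
  }
  out
}

# Location strings: "a..b", "complement(...)", "join(a..b,c..d)", single
# base "a". The feature span is the union of all parts; 1-based inclusive
# converted to 0-based half-open.
parse_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  body <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  body <- gsub("[<>]", "", body)
  parts <- strsplit(body, ",")[[1]]
  bounds <- purrr::map(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (any(is.na(nums))) abort(paste0("unparseable location: ", loc))
    c(min(nums), max(nums))
  })
  lo <- min(purrr::map_int(bounds, 1))
  hi <- max(purrr::map_int(bounds, 2))
  list(start = lo - 1L, end = hi, strand = strand)
}

#' Summary statistics for an annotated genome
#'
#' Computes the usual genome-table row: total length, GC percentage and
#' feature-kind tallies. GC% is `100 * (G + C) / (A + C + G + T)`, ignoring
#' ambiguity codes, rounded to one decimal — the convention used in
#' published organelle genome tables.
#'
#' @param genome An `annotated_genome`.
#' @return A one-row tibble: `species_id`, `total_bp`, `gc_percent`,
#'   `n_cds`, `n_trna`, `n_rrna`, `n_introns`.
#' @export
genome_summary <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  s <- genome$sequence
  if (nchar(s) == 0) abort("zero-length sequence")
  counts <- table(strsplit(s, "")[[1]])
  base <- function(b) if (b %in% names(counts)) as.integer(counts[[b]]) else 0L
  acgt <- base("A") + base("C") + base("G") + base("T")
  if (acgt == 0) abort("sequence has no unambiguous bases")
  gc <- round(100 * (base("G") + base("C")) / acgt, 1)
  f <- genome$features
  tibble(
    species_id = genome$species_id,
    total_bp = nchar(s),
    gc_percent = gc,
    n_cds = sum(f$kind == "CDS"),
    n_trna = sum(f$kind == "tRNA"),
    n_rrna = sum(f$kind == "rRNA"),
    n_introns = sum(f$kind == "intron")
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$species_id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}
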