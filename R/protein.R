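AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy index
KD <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

check_protein <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) == 0) abort("empty protein sequence")
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad)) {
    abort(paste0("invalid amino acids: ", paste(bad, collapse = "")))
  }
  chars
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Mean hydropathy in an odd-width window centred at each position;
#' windows shrink at the termini rather than dropping positions, so the
#' profile has the same length as the sequence. `X` scores 0.
#'
#' @param seq Amino-acid sequence (single string, 20 letters + X).
#' @param window Odd window width, at least 5 and at most the sequence
#'   length. 19 is the classic choice for transmembrane detection.
#' @return A `hydropathy_profile` tibble: `position` (1-based), `score`.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  if (window %% 2 == 0 || window < 5) abort("window must be odd and >= 5")
  chars <- check_protein(seq)
  n <- length(chars)
  if (window > n) abort("window longer than sequence")
  kd <- unname(KD[chars])
  half <- (window - 1) / 2
  cum <- c(0, cumsum(kd))
  score <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    (cum[hi + 1] - cum[lo]) / (hi - lo + 1)
  }, numeric(1))
  new_tbl_subclass(tibble(position = seq_len(n), score = score),
                   "hydropathy_profile")
}

#' Hydropathy profile with transmembrane calls
#' @param object A `hydropathy_profile`.
#' @param threshold Threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hydropathy_profile <- function(object, threshold = 1.6, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "residue", y = "mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of positions above `threshold`; runs separated by fewer
#' than `merge_gap` positions are merged, and merged runs shorter than
#' `min_tm_length` are discarded. This is a transparent stand-in for an
#' HMM-based predictor: parameters are explicit and the behaviour is
#' exactly reproducible.
#'
#' @param profile A `hydropathy_profile`.
#' @param threshold Hydropathy cutoff (default 1.6).
#' @param min_tm_length Minimum segment length in residues (default 15).
#' @param merge_gap Runs closer than this many residues merge (default 3).
#' @return Tibble of segments: `start`, `end` (0-based half-open),
#'   `mean_hydropathy`; zero rows when no segment passes.
#' @export
predict_tm_segments <- function(profile, threshold = 1.6, min_tm_length = 15,
                                merge_gap = 3) {
  above <- profile$score > threshold
  if (!any(above)) {
    return(tibble(start = integer(), end = integer(),
                  mean_hydropathy = numeric()))
  }
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- tibble(start = starts[r$values], stop = stops[r$values])
  merged <- list(c(runs$start[[1]], runs$stop[[1]]))
  for (i in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    if (runs$start[[i]] - last[[2]] - 1L < merge_gap) {
      merged[[length(merged)]][2] <- runs$stop[[i]]
    } else {
      merged[[length(merged) + 1]] <- c(runs$start[[i]], runs$stop[[i]])
    }
  }
  out <- purrr::map(merged, function(m) {
    len <- m[[2]] - m[[1]] + 1L
    if (len < min_tm_length) return(NULL)
    tibble(start = m[[1]] - 1L, end = m[[2]],
           mean_hydropathy = mean(profile$score[m[[1]]:m[[2]]]))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    tibble(start = integer(), end = integer(), mean_hydropathy = numeric())
  } else {
    arrange(out, .data$start)
  }
}

#' N-terminal transit-peptide heuristic
#'
#' Chloroplast transit peptides are serine/threonine rich, depleted in
#' acidic residues, and very often start Met-Ala. The score over the first
#' 40 residues is `(S+T fraction) - (D+E fraction)`, plus a 0.1 bonus for
#' alanine at position 2; the call is yes when the score reaches `cutoff`.
#' This is a composition stand-in for TargetP/ChloroP — precomputed calls
#' from the real predictors can be supplied downstream instead.
#'
#' @param seq Amino-acid sequence.
#' @param cutoff Score cutoff for a positive call (default 0.15).
#' @return A list: `score`, `call` (logical), `too_short` (TRUE when the
#'   sequence is under 40 residues, in which case the call is no).
#' @export
transit_peptide_heuristic <- function(seq, cutoff = 0.15) {
  chars <- check_protein(seq)
  if (length(chars) < 40) {
    return(list(score = NA_real_, call = FALSE, too_short = TRUE))
  }
  nterm <- chars[1:40]
  score <- mean(nterm %in% c("S", "T")) - mean(nterm %in% c("D", "E")) +
    if (chars[[2]] == "A") 0.1 else 0
  list(score = score, call = score >= cutoff, too_short = FALSE)
}

#' Position-weight profile for the heme-oxygenase domain
#'
#' Builds a log-odds position-weight matrix from the packaged synthetic
#' toy alignment of heme-oxygenase-like domain sequences (an ungapped
#' 60-column alignment shipped under `extdata`; it stands in for a real
#' curated domain alignment and is labelled synthetic). The detection
#' cutoff is calibrated at build time as mean + 3 SD of best-placement
#' scores on shuffled copies of the alignment sequences, under a fixed
#' internal seed, so detection behaviour is deterministic.
#'
#' The null uses the same statistic as detection — the best placement over
#' all offsets — on shuffled triple-length copies of each alignment
#' sequence, so the calibration accounts for the maximum over placements a
#' full-length query presents.
#'
#' @param alignment_path Optional path to an alternative ungapped FASTA
#'   alignment.
#' @param pseudocount Per-cell pseudocount (default 0.5).
#' @param n_shuffles Shuffled copies per sequence for the null (default 30).
#' @return A `hemeo_profile` object: list with `pwm` (20 x L log2-odds
#'   matrix), `length`, `cutoff`, `null_mean`, `null_sd`.
#' @export
hemeo_profile <- function(alignment_path = NULL, pseudocount = 0.5,
                          n_shuffles = 30) {
  if (is.null(alignment_path)) {
    alignment_path <- system.file("extdata", "hemeo_domain_synthetic.fasta",
                                  package = "plastome")
  }
  seqs <- read_fasta(alignment_path)$sequence
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) abort("alignment sequences must share one length")
  L <- lens
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  counts <- apply(mat, 2, function(col) {
    table(factor(col, levels = AA20))
  })
  freq <- (counts + pseudocount) / (nrow(mat) + 20 * pseudocount)
  pwm <- log2(freq / (1 / 20))
  rownames(pwm) <- AA20
  score_one <- function(s) score_profile_best(s, pwm)$score
  null_scores <- with_local_seed(20180508, {
    unlist(purrr::map(seqs, function(s) {
      chars <- rep(strsplit(s, "")[[1]], 3)
      purrr::map_dbl(seq_len(n_shuffles), function(i) {
        score_one(paste(sample(chars), collapse = ""))
      })
    }))
  })
  structure(
    list(pwm = pwm, length = L,
         cutoff = mean(null_scores) + 3 * sd(null_scores),
         null_mean = mean(null_scores), null_sd = sd(null_scores)),
    class = "hemeo_profile"
  )
}

score_profile_best <- function(seq, pwm) {
  chars <- check_protein(seq)
  L <- ncol(pwm)
  n <- length(chars)
  if (n < L) return(list(score = -Inf, start = NA_integer_))
  idx <- match(chars, rownames(pwm))
  best <- -Inf; at <- NA_integer_
  for (off in 0:(n - L)) {
    sub <- idx[(off + 1):(off + L)]
    ok <- !is.na(sub)
    s <- sum(pwm[cbind(sub[ok], which(ok))])
    if (s > best) { best <- s; at <- off }
  }
  list(score = best, start = at)
}

#' Locate the heme-oxygenase domain in a protein
#'
#' Best-scoring ungapped placement of the packaged position-weight
#' profile; reported only when the score reaches the profile's calibrated
#' shuffle-null cutoff.
#'
#' @param seq Amino-acid sequence.
#' @param profile A [hemeo_profile()] object.
#' @return A list `start`, `end` (0-based half-open), `score` when found;
#'   `NULL` when no placement passes the cutoff (including sequences
#'   shorter than the profile).
#' @export
detect_hemeo_domain <- function(seq, profile = hemeo_profile()) {
  hit <- score_profile_best(seq, profile$pwm)
  if (!is.finite(hit$score) || hit$score < profile$cutoff) return(NULL)
  list(start = hit$start, end = hit$start + profile$length, score = hit$score)
}

#' Architecture features of one protein
#'
#' Runs the hydropathy, transit-peptide and domain components and derives
#' the two positional flags the isotype rules use: `c_terminal_tm` (any
#' transmembrane segment within the last `c_terminal_window` residues) and
#' `internal_tm` (any segment overlapping the domain span).
#'
#' @param seq Amino-acid sequence.
#' @param encoded_in `"plastid"`, `"nucleus"` or `"unknown"`.
#' @param profile A [hemeo_profile()]; pass one explicitly when scoring
#'   many proteins to avoid rebuilding it.
#' @param window,threshold,min_tm_length,merge_gap Transmembrane
#'   parameters, see [hydropathy_profile()] and [predict_tm_segments()].
#' @param transit_cutoff See [transit_peptide_heuristic()].
#' @param c_terminal_window C-terminal window in residues (default 60).
#' @return An `architecture_features` list: `transit_peptide`,
#'   `transit_score`, `tm_segments` (tibble), `domain_span`,
#'   `c_terminal_tm`, `internal_tm`, `encoded_in`, `length`.
#' @export
protein_features <- function(seq, encoded_in = "unknown",
                             profile = hemeo_profile(), window = 19,
                             threshold = 1.6, min_tm_length = 15,
                             merge_gap = 3, transit_cutoff = 0.15,
                             c_terminal_window = 60) {
  encoded_in <- match.arg(encoded_in, c("plastid", "nucleus", "unknown"))
  n <- length(check_protein(seq))
  prof <- hydropathy_profile(seq, window = min(window, if (n %% 2) n else n - 1))
  tm <- predict_tm_segments(prof, threshold = threshold,
                            min_tm_length = min_tm_length,
                            merge_gap = merge_gap)
  transit <- transit_peptide_heuristic(seq, cutoff = transit_cutoff)
  domain <- detect_hemeo_domain(seq, profile)
  cterm_lo <- max(0, n - c_terminal_window)
  c_terminal_tm <- nrow(tm) > 0 && any(tm$end > cterm_lo)
  internal_tm <- !is.null(domain) && nrow(tm) > 0 &&
    any(tm$start < domain$end & tm$end > domain$start)
  structure(
    list(transit_peptide = transit$call, transit_score = transit$score,
         tm_segments = tm, domain_span = domain,
         c_terminal_tm = c_terminal_tm, internal_tm = internal_tm,
         encoded_in = encoded_in, length = n),
    class = "architecture_features"
  )
}

#' Classify a heme-oxygenase isotype from architecture features
#'
#' Rule-based call, in priority order on proteins with a detected
#' heme-oxygenase domain:
#' 1. transit peptide and no transmembrane segment -> `HMOX1`;
#' 2. C-terminal transmembrane segment *and* transit peptide -> `pbsA`
#'    with a conflict note (the nuclear-transferred pbsA architecture:
#'    plastid-type protein re-targeted with a transit peptide);
#' 3. plastid-encoded, C-terminal transmembrane, no transit -> `pbsA`;
#' 4. nucleus-encoded, C-terminal transmembrane -> `HMOX2`;
#' 5. otherwise `unclassified`.
#' Without a domain span the call is always `unclassified`.
#'
#' @param features An `architecture_features` object.
#' @return An `isotype_call` list: `isotype`, `evidence` (character vector
#'   of the features that fired or blocked).
#' @export
classify_isotype <- function(features) {
  stopifnot(inherits(features, "architecture_features"))
  ev <- character()
  if (is.null(features$domain_span)) {
    return(structure(list(isotype = "unclassified",
                          evidence = "no heme-oxygenase domain detected"),
                     class = "isotype_call"))
  }
  ev <- c(ev, "heme-oxygenase domain present")
  n_tm <- nrow(features$tm_segments)
  if (features$transit_peptide && n_tm == 0) {
    return(structure(list(isotype = "HMOX1",
                          evidence = c(ev, "transit peptide",
                                       "no transmembrane segment")),
                     class = "isotype_call"))
  }
  if (features$c_terminal_tm && features$transit_peptide) {
    return(structure(
      list(isotype = "pbsA",
           evidence = c(ev, "C-terminal transmembrane segment",
                        "conflict: transit peptide on a pbsA-type architecture")),
      class = "isotype_call"))
  }
  if (features$encoded_in == "plastid" && features$c_terminal_tm &&
      !features$transit_peptide) {
    return(structure(list(isotype = "pbsA",
                          evidence = c(ev, "plastid-encoded",
                                       "C-terminal transmembrane segment")),
                     class = "isotype_call"))
  }
  if (features$encoded_in == "nucleus" && features$c_terminal_tm) {
    ev <- c(ev, "nucleus-encoded", "C-terminal transmembrane segment")
    if (features$internal_tm) ev <- c(ev, "internal transmembrane segment")
    return(structure(list(isotype = "HMOX2", evidence = ev),
                     class = "isotype_call"))
  }
  structure(list(isotype = "unclassified",
                 evidence = c(ev, "no rule fired")),
            class = "isotype_call")
}

#' @export
print.isotype_call <- function(x, ...) {
  cat("<isotype_call> ", x$isotype, " [",
      paste(x$evidence, collapse = "; "), "]\n", sep = "")
  invisible(x)
}

#' Classify every protein in a FASTA file or tibble
#'
#' End-to-end isotype table. Sequence compartment is read from the
#' `encoded_in` column (tibble input) or from a `encoded_in=` tag in the
#' FASTA header; it defaults to `"unknown"`. When `external` is given
#' (a tibble or TSV path with columns `seq_id`, `transit_peptide`,
#' `c_terminal_tm`, `internal_tm`, `n_tm`, `domain_start`, `domain_end`),
#' those precomputed feature calls — e.g. from TargetP/ChloroP/TMHMM —
#' replace the built-in heuristics for the listed sequences.
#'
#' @param proteins FASTA path, or tibble with `seq_id`, `sequence` and
#'   optionally `encoded_in`.
#' @param external Optional precomputed feature calls (tibble or TSV path).
#' @param profile A [hemeo_profile()].
#' @param ... Passed to [protein_features()].
#' @return A tibble: `seq_id`, `encoded_in`, `transit_peptide`, `n_tm`,
#'   `c_terminal_tm`, `internal_tm`, `domain_start`, `domain_end`,
#'   `isotype`, `evidence` (collapsed with "; ").
#' @export
classify_proteins <- function(proteins, external = NULL,
                              profile = hemeo_profile(), ...) {
  if (is.character(proteins)) proteins <- read_fasta(proteins)
  if (!"encoded_in" %in% names(proteins)) {
    proteins$encoded_in <- extract_encoded_in(proteins$seq_id)
  }
  proteins$seq_id <- strip_header_tags(proteins$seq_id)
  ext <- NULL
  if (!is.null(external)) {
    ext <- if (is.character(external)) {
      readr::read_tsv(external, col_types = readr::cols(
        seq_id = "c", transit_peptide = "l", c_terminal_tm = "l",
        internal_tm = "l", n_tm = "i", domain_start = "i", domain_end = "i"
      ))
    } else external
  }
  purrr::pmap(proteins[c("seq_id", "sequence", "encoded_in")],
              function(seq_id, sequence, encoded_in) {
    if (!is.null(ext) && seq_id %in% ext$seq_id) {
      e <- ext[match(seq_id, ext$seq_id), ]
      feats <- structure(
        list(transit_peptide = e$transit_peptide, transit_score = NA_real_,
             tm_segments = if (e$n_tm > 0)
               tibble(start = NA_integer_, end = NA_integer_,
                      mean_hydropathy = NA_real_)[rep(1, e$n_tm), ]
             else tibble(start = integer(), end = integer(),
                         mean_hydropathy = numeric()),
             domain_span = if (!is.na(e$domain_start))
               list(start = e$domain_start, end = e$domain_end) else NULL,
             c_terminal_tm = e$c_terminal_tm, internal_tm = e$internal_tm,
             encoded_in = encoded_in, length = nchar(sequence)),
        class = "architecture_features")
    } else {
      feats <- protein_features(sequence, encoded_in = encoded_in,
                                profile = profile, ...)
    }
    call <- classify_isotype(feats)
    tibble(
      seq_id = seq_id, encoded_in = encoded_in,
      transit_peptide = feats$transit_peptide,
      n_tm = nrow(feats$tm_segments),
      c_terminal_tm = feats$c_terminal_tm,
      internal_tm = feats$internal_tm,
      domain_start = feats$domain_span$start %||% NA_integer_,
      domain_end = feats$domain_span$end %||% NA_integer_,
      isotype = call$isotype,
      evidence = paste(call$evidence, collapse = "; ")
    )
  }) |> bind_rows()
}

extract_encoded_in <- function(headers) {
  m <- stringr::str_match(headers, "encoded_in=(\\w+)")[, 2]
  ifelse(m %in% c("plastid", "nucleus"), m, "unknown")
}

strip_header_tags <- function(headers) {
  trimws(sub("\\s.*$", "", headers))
}

#' Read / write protein FASTA
#'
#' Minimal plain-text FASTA support: the full header line is kept in
#' `seq_id` on read, so tags like `encoded_in=plastid` survive.
#'
#' @param path File path.
#' @param proteins Tibble with `seq_id`, `sequence`.
#' @return `read_fasta()` returns a tibble `seq_id`, `sequence`;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  tibble(seq_id = names(set), sequence = unname(as.character(set)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(setNames(proteins$sequence,
                                         proteins$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
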