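#' Per-gene habitat-by-presence contingency table
#'
#' Tallies species into a 2x2 table with rows (marine, freshwater) and
#' columns (present, absent). Brackish species are excluded by default —
#' their count is recorded — or folded into either habitat via
#' `brackish_policy`, since surveys disagree on how to bin them and the
#' screen's denominator must be explicit.
#'
#' @param matrix A `presence_matrix`.
#' @param gene Gene symbol (a matrix column).
#' @param brackish_policy One of `"exclude"`, `"as_marine"`,
#'   `"as_freshwater"`.
#' @return A `contingency_table`: list with `counts` (2x2 integer matrix,
#'   dimnames habitat x presence), `gene` and `n_excluded_brackish`.
#' @export
contingency_table <- function(matrix, gene,
                              brackish_policy = c("exclude", "as_marine",
                                                  "as_freshwater")) {
  brackish_policy <- match.arg(brackish_policy)
  if (!gene %in% matrix_genes(matrix)) {
    abort(paste0("gene not in matrix: ", gene))
  }
  hab <- matrix$habitat
  n_brackish <- sum(hab == "brackish")
  eff <- dplyr::case_when(
    hab != "brackish" ~ hab,
    brackish_policy == "as_marine" ~ "marine",
    brackish_policy == "as_freshwater" ~ "freshwater",
    .default = NA_character_
  )
  keep <- !is.na(eff)
  if (!any(keep)) abort("no species left after brackish policy: empty table")
  present <- matrix[[gene]][keep]
  eff <- eff[keep]
  counts <- matrix(
    c(sum(eff == "marine" & present), sum(eff == "marine" & !present),
      sum(eff == "freshwater" & present), sum(eff == "freshwater" & !present)),
    nrow = 2, byrow = TRUE,
    dimnames = list(habitat = c("marine", "freshwater"),
                    presence = c("present", "absent"))
  )
  structure(
    list(counts = counts, gene = gene,
         n_excluded_brackish = if (brackish_policy == "exclude") n_brackish else 0L),
    class = "contingency_table"
  )
}

as_counts <- function(table) {
  if (inherits(table, "contingency_table")) return(table$counts)
  m <- as.matrix(table)
  stopifnot(identical(dim(m), c(2L, 2L)), all(m >= 0))
  m
}

#' Habitat-specific gene concordance rate
#'
#' The fraction of surveyed species whose presence/absence matches one of
#' the two habitat-specific patterns: retained in marine and lost in
#' freshwater (`marine_retained`), or the reverse
#' (`freshwater_retained`). The larger of the two complementary rates is
#' returned with its direction; ties break toward `marine_retained`. The
#' rate is therefore always at least 0.5.
#'
#' @param table A `contingency_table` or 2x2 matrix with rows
#'   (marine, freshwater) and columns (present, absent).
#' @return A list with `rate` (proportion in \[0.5, 1\]) and `direction`.
#' @export
concordance_rate <- function(table) {
  m <- as_counts(table)
  total <- sum(m)
  if (total == 0) abort("empty contingency table")
  rate_marine <- (m[1, 1] + m[2, 2]) / total
  if (rate_marine >= 0.5) {
    list(rate = rate_marine, direction = "marine_retained")
  } else {
    list(rate = 1 - rate_marine, direction = "freshwater_retained")
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson statistic with df = 1 and upper-tail p-value, optionally
#' with the Yates continuity adjustment. A table with a zero row or column
#' margin has no defined statistic; such tables come back flagged
#' degenerate with `chi2 = 0`, `p = 1` rather than raising, so
#' genome-wide screens never abort on an invariant gene.
#'
#' @param table A `contingency_table` or 2x2 count matrix.
#' @param correction Apply the Yates continuity correction?
#' @return A list: `chi2`, `df` (1), `p_value`, `degenerate`.
#' @export
chi_square_test <- function(table, correction = FALSE) {
  m <- as_counts(table)
  n <- sum(m)
  if (n == 0) abort("empty contingency table")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(chi2 = 0, df = 1L, p_value = 1, degenerate = TRUE))
  }
  expected <- outer(rs, cs) / n
  if (correction) {
    dev <- pmax(abs(m - expected) - 0.5, 0)
  } else {
    dev <- abs(m - expected)
  }
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, df = 1L,
       p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Screen every gene for habitat association
#'
#' The survey's statistical core: for each gene in the matrix, build the
#' habitat x presence contingency table, compute the concordance rate with
#' its direction and the chi-square p-value, and flag significance at
#' `alpha` (default 0.01, the survey cutoff). No multiple-testing
#' adjustment is applied by default; `adjust` exposes Bonferroni /
#' Benjamini-Hochberg on request (significance is then tested on the
#' adjusted p-values).
#'
#' @param matrix A `presence_matrix` with at least two habitats
#'   represented after applying `brackish_policy`.
#' @param alpha Significance cutoff on the (possibly adjusted) p-value.
#' @param brackish_policy See [contingency_table()].
#' @param correction Yates continuity correction, passed to
#'   [chi_square_test()].
#' @param adjust One of `"none"`, `"bonferroni"`, `"BH"`.
#' @return A `habitat_screen` tibble sorted by ascending p-value with
#'   columns `gene`, `marine_present`, `marine_absent`,
#'   `freshwater_present`, `freshwater_absent`, `concordance`,
#'   `direction`, `chi2`, `df`, `p_value`, `p_adjusted`, `degenerate`,
#'   `significant`. Screen settings are attached as attributes.
#' @export
screen_genes <- function(matrix, alpha = 0.01,
                         brackish_policy = c("exclude", "as_marine",
                                             "as_freshwater"),
                         correction = FALSE,
                         adjust = c("none", "bonferroni", "BH")) {
  brackish_policy <- match.arg(brackish_policy)
  adjust <- match.arg(adjust)
  genes <- matrix_genes(matrix)
  if (length(genes) == 0 || nrow(matrix) == 0) abort("empty matrix")
  probe <- contingency_table(matrix, genes[[1]], brackish_policy)
  if (any(rowSums(probe$counts) == sum(probe$counts))) {
    abort("only one habitat represented: association is undefined")
  }
  rows <- purrr::map(genes, function(g) {
    ct <- contingency_table(matrix, g, brackish_policy)
    conc <- concordance_rate(ct)
    test <- chi_square_test(ct, correction = correction)
    tibble(
      gene = g,
      marine_present = ct$counts[1, 1], marine_absent = ct$counts[1, 2],
      freshwater_present = ct$counts[2, 1], freshwater_absent = ct$counts[2, 2],
      concordance = conc$rate, direction = conc$direction,
      chi2 = test$chi2, df = test$df, p_value = test$p_value,
      degenerate = test$degenerate
    )
  })
  out <- bind_rows(rows)
  out$p_adjusted <- if (adjust == "none") out$p_value else
    stats::p.adjust(out$p_value, method = adjust)
  # alpha = 1 disables the cutoff entirely (degenerate genes carry p = 1)
  out$significant <- out$p_adjusted < alpha | alpha >= 1
  out <- arrange(out, .data$p_value, .data$gene)
  structure(
    new_tbl_subclass(out, "habitat_screen"),
    alpha = alpha, brackish_policy = brackish_policy,
    correction = correction, adjust = adjust,
    n_excluded_brackish = probe$n_excluded_brackish
  )
}

new_tbl_subclass <- function(x, cls) {
  class(x) <- c(cls, class(tibble()))
  x
}

#' @export
tidy.habitat_screen <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.habitat_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    brackish_policy = attr(x, "brackish_policy"),
    correction = attr(x, "correction"),
    adjust = attr(x, "adjust"),
    n_excluded_brackish = attr(x, "n_excluded_brackish")
  )
}

#' Concordance / significance overview of a habitat screen
#'
#' Scatter of per-gene concordance rate against -log10 p-value; genes
#' passing the screen cutoff are highlighted and labelled.
#'
#' @param object A `habitat_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.habitat_screen <- function(object, ...) {
  df <- mutate(as_tibble(object),
               neglog10p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concordance,
                                   y = .data$neglog10p,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_text(
      data = filter(df, .data$significant),
      ggplot2::aes(label = .data$gene),
      vjust = -0.7, size = 3, show.legend = FALSE
    ) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey55")) +
    ggplot2::labs(x = "habitat concordance rate",
                  y = expression(-log[10] ~ p),
                  color = paste0("p < ", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
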