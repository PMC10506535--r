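# Pathologist-survey analysis: interobserver agreement (Fleiss' kappa with
# a large-sample 95% CI) and per-rater score summaries.

#' Ratings table
#'
#' Items-by-raters matrix of categorical ratings (every cell filled, same
#' rater count per item) with its category set and an optional condition
#' tag distinguishing virtual from real stain images.
#'
#' @param ratings Items x raters matrix (character, factor or numeric).
#' @param categories Declared category set (default: sorted unique values).
#' @param condition `"virtual"`, `"real"` or `NA`.
#' @return A `ratings_table`.
#' @export
ratings_table <- function(ratings, categories = NULL, condition = NA) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("every cell must be filled")
  vals <- sort(unique(as.vector(ratings)))
  if (is.null(categories)) categories <- vals
  if (!all(vals %in% categories)) {
    stop("ratings outside the declared category set: ",
         paste(setdiff(vals, categories), collapse = ", "))
  }
  structure(list(ratings = ratings, categories = categories,
                 condition = condition), class = "ratings_table")
}

#' Read a long-format ratings CSV
#'
#' Expects columns `item_id`, `rater_id`, `rating` and optionally
#' `condition`; pivots to one [ratings_table()] per condition.
#'
#' @param path CSV path.
#' @return A `ratings_table`, or a named list of them when the file holds
#'   several conditions.
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "rater_id", "rating")
  if (!all(need %in% names(df))) {
    stop("ratings CSV needs columns: ", paste(need, collapse = ", "))
  }
  split_by <- if ("condition" %in% names(df)) df$condition else "all"
  out <- lapply(split(df, split_by), function(d) {
    m <- tapply(d$rating, list(d$item_id, d$rater_id), function(v) v[1])
    ratings_table(m, condition = d$condition[1] %||% NA)
  })
  if (length(out) == 1) out[[1]] else out
}

# Item-by-category count matrix from a ratings table.
.category_counts <- function(table) {
  r <- table$ratings
  ncat <- length(table$categories)
  m <- vapply(seq_len(nrow(r)), function(i) {
    tabulate(match(r[i, ], table$categories), nbins = ncat)
  }, integer(ncat))
  # vapply simplifies a length-1 FUN.VALUE to a vector; keep items as rows
  t(matrix(m, nrow = ncat))
}

#' Fleiss' kappa with a 95% confidence interval
#'
#' Chance-corrected multi-rater agreement: kappa = (P_bar - P_e) /
#' (1 - P_e), where P_bar is the mean over items of the pairwise agreement
#' proportion and P_e is the sum of squared category marginals. The
#' variance uses the standard Fleiss large-sample formula and the CI the
#' normal approximation.
#'
#' @param table A [ratings_table()] (or bare items x raters matrix) with at
#'   least 2 raters, 2 items and 2 categories used overall.
#' @return A `kappa_result`: `kappa`, `ci_low`, `ci_high`, `se`,
#'   `n_items`, `n_raters`, `interpretation`.
#' @export
fleiss_kappa <- function(table) {
  if (!inherits(table, "ratings_table")) table <- ratings_table(table)
  counts <- .category_counts(table)
  N <- nrow(counts)
  r <- rowSums(counts)[1]
  if (N < 2 || r < 2) stop("need >= 2 items and >= 2 raters")
  if (any(rowSums(counts) != r)) stop("same rater count required per item")
  pj <- colSums(counts) / (N * r)
  if (sum(pj > 0) < 2) {
    stop("kappa undefined: all ratings fall in one category (P_e = 1)")
  }
  Pi <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  kappa <- (Pbar - Pe) / (1 - Pe)
  # Fleiss, Nee & Landis large-sample variance under the null-structure
  # approximation
  varK <- 2 / (N * r * (r - 1)) *
    (Pe - (2 * r - 3) * Pe^2 + 2 * (r - 2) * sum(pj^3)) / (1 - Pe)^2
  se <- sqrt(max(varK, 0))
  z <- qnorm(0.975)
  structure(list(
    kappa = kappa, ci_low = kappa - z * se, ci_high = kappa + z * se,
    se = se, n_items = N, n_raters = r,
    interpretation = interpret_kappa(kappa),
    condition = table$condition
  ), class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %.3f (95%% CI %.3f-%.3f), %s agreement\n",
              x$kappa, x$ci_low, x$ci_high, x$interpretation))
  cat(sprintf("  %d items, %d raters\n", x$n_items, x$n_raters))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kappa_result <- function(x, ...) {
  data.frame(kappa = x$kappa, ci_low = x$ci_low, ci_high = x$ci_high,
             se = x$se, n_items = x$n_items, n_raters = x$n_raters,
             interpretation = x$interpretation)
}

#' Interpretation band of a kappa value
#'
#' The conventional agreement bands: 0.01-0.20 none to slight, 0.21-0.40
#' fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 almost
#' perfect; zero or below is agreement by chance (or worse).
#'
#' @param value Kappa (<= 1).
#' @return Band label, character.
#' @export
interpret_kappa <- function(value) {
  if (value > 1) stop("kappa cannot exceed 1")
  if (value <= 0) return("chance or worse")
  if (value <= 0.20) return("none to slight")
  if (value <= 0.40) return("fair")
  if (value <= 0.60) return("moderate")
  if (value <= 0.80) return("substantial")
  "almost perfect"
}

#' Summarise numeric quality scores per rater
#'
#' Mean and SD (n - 1 denominator) per rater and pooled over all cells,
#' formatted `"m.mm +/- s.ss"`, plus a two-sided paired t comparison of the
#' virtual and real conditions per rater when both are supplied.
#'
#' @param virtual A [ratings_table()] with numeric categories.
#' @param real Optional second table, same raters, for the paired
#'   comparison (items paired by position).
#' @return A `score_summary`: data frame `per_rater`, row `overall`, and
#'   (with two conditions) data frame `comparison` with `t` and `p`.
#' @export
summarize_scores <- function(virtual, real = NULL) {
  as_num <- function(tb) {
    v <- suppressWarnings(apply(tb$ratings, 2, as.numeric))
    if (any(is.na(v))) {
      stop("non-numeric score categories; use fleiss_kappa for categorical data")
    }
    v
  }
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  one <- function(v, cond) {
    per <- data.frame(
      rater = colnames(v) %||% paste0("rater", seq_len(ncol(v))),
      condition = cond,
      mean = colMeans(v), sd = apply(v, 2, sd)
    )
    per$label <- fmt(per$mean, per$sd)
    overall <- data.frame(rater = "overall", condition = cond,
                          mean = mean(v), sd = sd(as.vector(v)))
    overall$label <- fmt(overall$mean, overall$sd)
    rbind(per, overall)
  }
  v <- as_num(virtual)
  out <- one(v, "virtual")
  comparison <- NULL
  if (!is.null(real)) {
    rv <- as_num(real)
    out <- rbind(out, one(rv, "real"))
    if (nrow(rv) != nrow(v) || ncol(rv) != ncol(v)) {
      stop("paired comparison needs matching table dimensions")
    }
    comparison <- do.call(rbind, lapply(seq_len(ncol(v)), function(j) {
      d <- v[, j] - rv[, j]
      if (sd(d) == 0) {
        data.frame(rater = j, t = 0, df = length(d) - 1, p = 1)
      } else {
        t <- mean(d) / (sd(d) / sqrt(length(d)))
        data.frame(rater = j, t = t, df = length(d) - 1,
                   p = 2 * pt(-abs(t), length(d) - 1))
      }
    }))
  }
  structure(list(scores = out, comparison = comparison),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  df <- x$scores
  for (cond in unique(df$condition)) {
    cat(cond, "stain scores:\n")
    sub <- df[df$condition == cond, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-8s %s\n", sub$rater[i], sub$label[i]))
    }
  }
  if (!is.null(x$comparison)) {
    cat("paired virtual-vs-real per rater:\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}
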