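#' Spearman rank correlation with exact permutation P for small n
#'
#' Computes Spearman's rho with average ranks for ties. For `n <= exact_n`
#' (default 9) the two-sided P value is computed exactly by enumerating all
#' `n!` rank permutations of one variable; for larger n the asymptotic
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom is used.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @param exact_n largest n for which the exact permutation null is
#'   enumerated.
#' @return list with `rho`, `p`, `n`, `method` (`"exact"` or
#'   `"asymptotic"`).
#' @export
spearman_test <- function(x, y, exact_n = 9L) {
  if (length(x) != length(y)) stop("paired vectors required", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman's rho undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    perms <- permutations_of(n)
    num <- matrix(ryc[perms], nrow = nrow(perms)) %*% rxc
    rho_null <- as.vector(num) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(rho = rho, p = min(p, 1), n = n, method = "asymptotic")
}

# all permutations of 1..n as a (n! x n) integer matrix
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation network between photon parameters and endpoints
#'
#' Tests every (parameter, endpoint) pair with [spearman_test()] and keeps
#' an edge wherever `P <= threshold`. Edges carry rho, P and the sign of
#' rho, matching the usual network-figure conventions (solid positive /
#' dotted negative, width by `|rho|`). Pairs with a constant vector are
#' skipped with a warning.
#'
#' @param parameters data.frame of numeric per-sample photon parameters
#'   (columns = nodes); non-numeric `sample_id`/`group` columns ignored.
#' @param endpoints data.frame of numeric per-sample quality/physiology
#'   endpoints, same row order.
#' @param threshold significance threshold on P (default 0.05).
#' @return Object of class `correlation_network`: list with `nodes`
#'   (data.frame: name, type) and `edges` (data.frame: source, target,
#'   rho, p, sign), plus `threshold` and `all_pairs` (unfiltered tests).
#' @export
spearman_network <- function(parameters, endpoints, threshold = 0.05) {
  p_df <- numeric_cols(parameters)
  e_df <- numeric_cols(endpoints)
  if (nrow(p_df) != nrow(e_df))
    stop("parameters and endpoints must cover the same samples", call. = FALSE)
  res <- NULL
  for (pn in names(p_df)) for (en in names(e_df)) {
    tst <- tryCatch(spearman_test(p_df[[pn]], e_df[[en]]),
                    error = function(e) {
                      warning("skipping pair (", pn, ", ", en, "): ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(tst)) next
    res <- rbind(res, data.frame(source = pn, target = en, rho = tst$rho,
                                 p = tst$p, sign = sign(tst$rho),
                                 stringsAsFactors = FALSE))
  }
  edges <- res[!is.na(res$p) & res$p <= threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    name = c(names(p_df), names(e_df)),
    type = rep(c("parameter", "endpoint"), c(ncol(p_df), ncol(e_df))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 all_pairs = res),
            class = "correlation_network")
}

numeric_cols <- function(df) {
  df <- as.data.frame(df)
  df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE]
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("Correlation network: %d nodes, %d edges at P <= %g\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Export a correlation network
#'
#' `network_to_igraph()` converts to an igraph object (edge attributes
#' `rho`, `p`, `sign`, node attribute `type`); `write_network_graphml()`
#' writes GraphML; `write_network_csv()` writes the edge list as CSV
#' (`source, target, rho, p, sign`).
#'
#' @param network a `correlation_network`.
#' @param path output file path.
#' @return The igraph object, or `path` invisibly for the writers.
#' @export
network_to_igraph <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' @rdname network_to_igraph
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network_to_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname network_to_igraph
#' @export
write_network_csv <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pharmacopoeial quality classification by indirubin content
#'
#' Flags each group against the pharmacopoeial marker-compound standard:
#' a group fails when its indirubin content falls below the threshold
#' (default 0.02% w/w). A content exactly at the threshold passes
#' (>= rule).
#'
#' @param content_table data.frame with a `group` column and an
#'   `indirubin` column (content in % w/w), one row per group (or per
#'   sample).
#' @param threshold minimum acceptable content, % (default 0.02).
#' @return data.frame with `group`, `indirubin`, `pass`.
#' @export
classify_quality <- function(content_table, threshold = 0.02) {
  df <- as.data.frame(content_table)
  if (!"indirubin" %in% names(df))
    stop("content table lacks an 'indirubin' column", call. = FALSE)
  if (any(df$indirubin < 0))
    stop("contents must be >= 0", call. = FALSE)
  data.frame(group = df$group, indirubin = df$indirubin,
             pass = df$indirubin >= threshold,
             stringsAsFactors = FALSE)
}
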