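# Hypergeometric over-representation analysis of a significant-metabolite
# list against a pathway library.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of drawing at least `k` pathway members when `n`
#' metabolites are sampled without replacement from a universe of `N` of
#' which `K` belong to the pathway:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Computed through [stats::phyper()], which works in log space internally.
#'
#' @param k Hits in the list.
#' @param K Pathway size within the universe.
#' @param n List size.
#' @param N Universe size.
#' @return Exact tail probability in (0, 1].
#' @export
ora_pvalue <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 1) stop("counts must be non-negative", call. = FALSE)
  if (K > N || n > N) stop("K and n cannot exceed N", call. = FALSE)
  if (k > min(K, n)) stop("k cannot exceed min(K, n)", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a pathway library
#'
#' Supports a JSON layout (`pathways: {id: {name, members}}` plus optional
#' `universe_extra` background ids) and plain GMT (one pathway per line:
#' id, description, members, tab-separated).
#'
#' @param path File path (`.json` or `.gmt`).
#' @return A `pathway_library`: list with `pathways` (id -> list(name,
#'   members)) and `universe` (character vector).
#' @export
read_pathway_library <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    pw <- lapply(raw$pathways, function(p)
      list(name = p$name, members = as.character(p$members)))
    extra <- as.character(raw$universe_extra %||% character(0))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    pw <- stats::setNames(
      lapply(parts, function(p) list(name = p[2], members = p[-(1:2)])),
      vapply(parts, `[`, character(1), 1))
    extra <- character(0)
  }
  if (any(vapply(pw, function(p) length(p$members) == 0L, logical(1)))) {
    stop("pathway library contains an empty pathway", call. = FALSE)
  }
  universe <- sort(unique(c(unlist(lapply(pw, `[[`, "members")), extra)))
  structure(list(pathways = pw, universe = universe),
            class = "pathway_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The bundled five-pathway example library
#'
#' A compact curated library (sphingolipid, taurine/hypotaurine, nitrogen,
#' cysteine/methionine and glycerophospholipid metabolism) with HMDB-coded
#' members and a synthetic background universe, shipped for examples and
#' tests.
#'
#' @return A `pathway_library`.
#' @export
bundled_pathway_library <- function() {
  read_pathway_library(system.file("extdata", "pathway_library.json",
                                   package = "chemomet", mustWork = TRUE))
}

#' Pathway enrichment of a metabolite list
#'
#' One hypergeometric test per pathway; raw p-values are compared against
#' `alpha` (no multiple-testing adjustment by default, `adjust = "BH"` is
#' available). List ids absent from the universe are dropped with a warning.
#'
#' @param list_ids Character vector of significant metabolite ids (HMDB).
#' @param library A `pathway_library`.
#' @param alpha Significance level on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Data frame sorted by p-value: pathway id/name, k, K, n, N,
#'   p_value, significant flag, and semicolon-joined hit ids.
#' @export
enrich <- function(list_ids, library, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(library, "pathway_library"))
  list_ids <- unique(as.character(list_ids))
  if (length(list_ids) == 0L) stop("empty metabolite list", call. = FALSE)
  known <- list_ids %in% library$universe
  if (any(!known)) {
    warning(sum(!known), " list id(s) not in universe, dropped: ",
            paste(utils::head(list_ids[!known], 5), collapse = ", "))
    list_ids <- list_ids[known]
  }
  if (length(list_ids) == 0L) stop("no list ids found in universe", call. = FALSE)
  N <- length(library$universe)
  n <- length(list_ids)
  rows <- lapply(names(library$pathways), function(id) {
    p <- library$pathways[[id]]
    hits <- intersect(list_ids, p$members)
    K <- length(intersect(p$members, library$universe))
    data.frame(pathway = id, name = p$name,
               k = length(hits), K = K, n = n, N = N,
               p_value = ora_pvalue(length(hits), K, n, N),
               hits = paste(hits, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_eff <- if (identical(adjust, "none")) res$p_value else
    stats::p.adjust(res$p_value, method = adjust)
  res$p_adjusted <- if (identical(adjust, "none")) NA_real_ else p_eff
  res$significant <- p_eff < alpha
  res[order(res$p_value), , drop = FALSE]
}
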