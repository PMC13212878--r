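#' Read a GMT gene-set library
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are uppercased and
#' deduplicated; lines with fewer than three fields are a parse error.
#'
#' @param path GMT file path.
#' @return list of class `gene_set_library`: `sets` (named list of member
#'   vectors), `source` (path).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_gmt: no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("read_gmt: line %d has fewer than 3 tab-separated fields", i))
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("read_gmt: line %d defines an empty set", i))
    sets[[fields[1]]] <- members
  }
  structure(list(sets = sets, source = path), class = "gene_set_library")
}

#' Write a GMT gene-set library
#'
#' @param library a `gene_set_library` or named list of member vectors.
#' @param path output path.
#' @param descriptions optional per-set description (default `"na"`).
#' @return the path, invisibly.
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  sets <- if (inherits(library, "gene_set_library")) library$sets else library
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Fisher-exact over-representation analysis against a GMT library
#'
#' For each gene set, a one-sided (enrichment) Fisher exact test of the
#' 2x2 in-query x in-set table over the background universe, computed as the
#' hypergeometric upper tail; BH adjustment across all sets tested. The odds
#' ratio is the cross-product ratio with a Haldane 0.5 correction when any
#' cell is zero. The background defaults to all proteins quantified in the
#' run, not the genome, since enrichment panels are a biased universe.
#'
#' @param query character vector of query identifiers (uppercased).
#' @param background character vector of background identifiers
#'   (`query` must be a subset).
#' @param library a `gene_set_library` or named list of sets.
#' @param q_threshold report sets with BH q below this value (default 0.01;
#'   use 1 to keep all).
#' @return data.frame sorted by q: `set`, `set_size`, `overlap_count`,
#'   `odds_ratio`, `p`, `q`, `overlap_members` (comma-joined). Attribute
#'   `"all"` holds the unfiltered table.
#' @export
ora <- function(query, background, library, q_threshold = 0.01) {
  sets <- if (inherits(library, "gene_set_library")) library$sets else library
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  offenders <- setdiff(query, background)
  if (length(offenders))
    stop(sprintf("ora: query not a subset of background: %s",
                 paste(head(offenders, 5), collapse = ", ")))
  N <- length(background); nq <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    K <- length(members)
    ov <- intersect(query, members)
    a <- length(ov)                    # in query, in set
    b <- nq - a                        # in query, not in set
    cc <- K - a                        # not in query, in set
    d <- N - nq - cc
    p <- phyper(a - 1, K, N - K, nq, lower.tail = FALSE)
    or <- if (a == 0 || b == 0 || cc == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    else (a * d) / (b * cc)
    data.frame(set = nm, set_size = K, overlap_count = a, odds_ratio = or,
               p = p, overlap_members = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set),
             c("set", "set_size", "overlap_count", "odds_ratio", "p", "q",
               "overlap_members")]
  rownames(out) <- NULL
  filtered <- out[out$q < q_threshold, , drop = FALSE]
  attr(filtered, "all") <- out
  filtered
}
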