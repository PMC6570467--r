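#' Hypergeometric upper-tail probability for set over-representation
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` pathway members when `n` significant features are drawn
#' without replacement from a universe of `N` features of which `K` belong
#' to the pathway.
#'
#' @param k observed overlap.
#' @param K pathway size within the universe.
#' @param n number of selected (significant) features.
#' @param N universe size.
#' @return upper-tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read / write GMT pathway files
#'
#' GMT is one pathway per line: id, description, then tab-separated member
#' ids.
#'
#' @param path file path.
#' @return for `read_gmt`, a named list of member-id character vectors with
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in GMT", call. = FALSE)
  desc <- vapply(parts, `[`, character(1), 2)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (any(lengths(members) == 0))
    stop("pathway with no members in GMT", call. = FALSE)
  names(members) <- ids
  names(desc) <- ids
  structure(members, description = desc)
}

#' @rdname read_gmt
#' @param pathways named list of member-id vectors.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(pathways)),
                                    names(pathways))
  lines <- vapply(names(pathways), function(id) {
    paste(c(id, descriptions[[id]], pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a selected set against pathway sets
#'
#' For each pathway with at least one member in the universe, tests whether
#' the selected features overlap the pathway more than expected under the
#' hypergeometric null, then applies Benjamini-Hochberg correction across
#' tested pathways. The universe is restricted to features mapped to at
#' least one pathway; unmapped selected features are counted and reported
#' in `attr(, "unmapped")` (they are discarded from the test, as is
#' conventional).
#'
#' @param selected character vector of significant feature ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all measured feature ids.
#' @param db named list of pathway member-id vectors (see [read_gmt()]).
#' @return data frame with columns `pathway`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   sorted by `p` then pathway id; unmapped id counts in
#'   `attr(, "unmapped")`.
#' @export
enrich <- function(selected, universe, db) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("'selected' must be a subset of 'universe'", call. = FALSE)
  if (length(selected) == 0)
    warning("empty selected set: all p-values are 1", call. = FALSE)
  mapped_ids <- unique(unlist(db, use.names = FALSE))
  uni <- intersect(universe, mapped_ids)
  sel <- intersect(selected, uni)
  unmapped <- c(selected = length(selected) - length(sel),
                universe = length(universe) - length(uni))
  N <- length(uni)
  n <- length(sel)

  K <- vapply(db, function(m) length(intersect(m, uni)), integer(1))
  tested <- names(db)[K >= 1]
  if (length(tested) == 0) {
    warning("no pathway overlaps the universe", call. = FALSE)
    out <- data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0))
    return(structure(out, unmapped = unmapped))
  }
  k <- vapply(db[tested], function(m) length(intersect(m, sel)), integer(1))
  p <- mapply(hypergeom_tail, k = k, K = K[tested],
              MoreArgs = list(n = n, N = N))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pathway = tested, k = k, K = K[tested], n = n, N = N,
                    p = p, q = q, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, unmapped = unmapped)
}

#' Joint multi-omics over-representation with per-omics support flags
#'
#' Pools the significant genes, proteins and metabolites (after optional
#' id mapping into the shared pathway namespace) into one selected set and
#' the measured features into one universe, runs [enrich()] on the pooled
#' sets, and flags for every pathway which omics layers contribute at least
#' one overlapping member. The flags reproduce the three-color reading of
#' pathway support: all three omics, proteins and genes only, or genes only.
#' A `mode = "separate"` variant returns one enrichment table per omics
#' layer instead of the pooled test.
#'
#' @param gene_sel,prot_sel,met_sel selected (significant) ids per omics.
#' @param gene_univ,prot_univ,met_univ measured universes per omics.
#' @param db named list of pathway member-id vectors.
#' @param id_maps optional named list of named character vectors
#'   (`gene`, `protein`, `metabolite`) mapping omics-local ids into the
#'   pathway namespace; identity where absent. An omics whose map covers
#'   none of its ids is excluded with a warning.
#' @param mode `"pooled"` (default) or `"separate"`.
#' @return for `"pooled"`, the [enrich()] table plus logical columns
#'   `gene_support`, `protein_support`, `metabolite_support`; for
#'   `"separate"`, a named list of per-omics [enrich()] tables.
#' @export
multiomics_enrich <- function(gene_sel, prot_sel, met_sel,
                              gene_univ, prot_univ, met_univ, db,
                              id_maps = NULL,
                              mode = c("pooled", "separate")) {
  mode <- match.arg(mode)
  remap_layer <- function(sel, univ, omics) {
    map <- id_maps[[omics]]
    if (is.null(map)) return(list(sel = unique(sel), univ = unique(univ)))
    if (length(univ) > 0 && !any(univ %in% names(map))) {
      warning("no id mapping for omics '", omics, "'; layer excluded",
              call. = FALSE)
      return(list(sel = character(0), univ = character(0)))
    }
    list(sel = unique(unname(map[sel[sel %in% names(map)]])),
         univ = unique(unname(map[univ[univ %in% names(map)]])))
  }
  layers <- list(
    gene = remap_layer(gene_sel, gene_univ, "gene"),
    protein = remap_layer(prot_sel, prot_univ, "protein"),
    metabolite = remap_layer(met_sel, met_univ, "metabolite")
  )
  if (all(vapply(layers, function(l) length(l$sel), integer(1)) == 0))
    warning("all omics selected sets are empty", call. = FALSE)

  if (mode == "separate") {
    return(lapply(layers, function(l) enrich(l$sel, l$univ, db)))
  }

  sel <- unique(unlist(lapply(layers, `[[`, "sel"), use.names = FALSE))
  univ <- unique(c(unlist(lapply(layers, `[[`, "univ"), use.names = FALSE),
                   sel))
  out <- enrich(sel, univ, db)
  for (omics in names(layers)) {
    flag <- vapply(out$pathway, function(pw) {
      length(intersect(db[[pw]], layers[[omics]]$sel)) > 0
    }, logical(1))
    out[[paste0(omics, "_support")]] <- unname(flag)
  }
  out
}
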