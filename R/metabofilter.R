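ec_field_re <- "([0-9]+|-)"
ec_re <- sprintf("^[1-7]\\.%s\\.%s\\.%s$", ec_field_re, ec_field_re,
                 ec_field_re)

is_valid_ec <- function(ec) {
  ok <- grepl(ec_re, ec)
  # numbered fields must be positive
  parts <- strsplit(ec, ".", fixed = TRUE)
  ok & vapply(parts, function(p) {
    num <- suppressWarnings(as.integer(p[p != "-"]))
    length(p) == 4 && !anyNA(num) && all(num >= 1)
  }, logical(1))
}

#' Parse a two-column gene-to-EC annotation file
#'
#' Reads a TSV with columns gene symbol and EC number (one EC per row) and
#' aggregates rows by gene. Malformed EC rows are rejected and collected
#' (with their line numbers) rather than failing the whole file.
#'
#' @param path path to a two-column TSV (gene, EC), no header by default.
#' @param header whether the file carries a header row.
#' @return named list mapping each gene symbol to its character vector of EC
#'   numbers, with rejected rows in `attr(, "rejected")` (data frame `line`,
#'   `gene`, `ec`).
#' @export
parse_ec_map <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("cannot read EC map: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = c("gene", "ec"),
                          colClasses = "character", quote = "",
                          blank.lines.skip = FALSE)
  if (nrow(df) == 0) {
    warning("empty EC map: ", path, call. = FALSE)
    return(structure(list(),
                     rejected = data.frame(line = integer(0),
                                           gene = character(0),
                                           ec = character(0))))
  }
  ok <- is_valid_ec(df$ec)
  rejected <- data.frame(line = which(!ok) + as.integer(header),
                         gene = df$gene[!ok], ec = df$ec[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " malformed EC row(s) rejected (see attr ",
            "'rejected')", call. = FALSE)
  df <- df[ok, , drop = FALSE]
  ann <- lapply(split(df$ec, df$gene), function(e) sort(unique(e)))
  structure(ann[order(names(ann), method = "radix")], rejected = rejected)
}

#' Default EC exclusion rules for macromolecule-substrate enzymes
#'
#' EC prefixes covering enzymes that act on proteins or nucleic acids rather
#' than small molecules: protein kinases (2.7.10-2.7.13), peptidases (3.4),
#' RNA/DNA polymerases and reverse transcriptase (2.7.7.6/7/49),
#' topoisomerases (5.6.2), tRNA ligases (6.1.1), ribonucleases
#' (3.1.26/3.1.27), nucleic-acid motor ATPases (3.6.4), and the ubiquitin
#' ligase 2.3.2.27. Shipped as an editable TSV
#' (`system.file("extdata", "ec_exclusions.tsv", package = "metaprior")`).
#'
#' @return data frame with columns `prefix` and `reason`.
#' @export
default_exclusion_rules <- function() {
  path <- system.file("extdata", "ec_exclusions.tsv", package = "metaprior")
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "")
}

ec_matches_prefix <- function(ec, prefix) {
  # prefix matching on whole dot-separated fields
  startsWith(paste0(ec, "."), paste0(prefix, "."))
}

#' Does an EC number describe a small-molecule transformation?
#'
#' Returns `FALSE` exactly when the EC number matches one of the exclusion
#' prefixes (enzymes using proteins or nucleic acids as substrates), `TRUE`
#' otherwise. An empty rule set excludes nothing.
#'
#' @param ec a valid EC number string (fields may be `"-"`).
#' @param rules exclusion rules, a data frame with a `prefix` column;
#'   defaults to [default_exclusion_rules()].
#' @return logical flag.
#' @export
is_small_molecule_ec <- function(ec, rules = default_exclusion_rules()) {
  if (!is_valid_ec(ec)) stop("invalid EC number: ", ec, call. = FALSE)
  if (is.null(rules) || nrow(rules) == 0) return(TRUE)
  !any(vapply(rules$prefix, function(p) ec_matches_prefix(ec, p),
              logical(1)))
}

#' Select metabolic genes from an EC annotation
#'
#' A gene is metabolic if at least one of its EC numbers survives the
#' exclusion rules (the inclusive reading: a gene with one protein-kinase EC
#' and one dehydrogenase EC is retained). Selection is monotone in the rule
#' list: removing a rule can only grow the selected set, and re-filtering an
#' already filtered annotation is a no-op.
#'
#' @param ann named list gene -> EC vector, as from [parse_ec_map()].
#' @param rules exclusion rules data frame (see
#'   [default_exclusion_rules()]).
#' @return sorted character vector of selected gene symbols.
#' @export
select_metabolic_genes <- function(ann, rules = default_exclusion_rules()) {
  keep <- vapply(ann, function(ecs) {
    any(vapply(ecs, is_small_molecule_ec, logical(1), rules = rules))
  }, logical(1))
  sort(names(ann)[keep], method = "radix")
}
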