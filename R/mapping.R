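#' Gene-label to species-label mapping rules
#'
#' Gene trees carry gene labels; the method needs the species each gene comes
#' from. Three conventions are supported:
#' \describe{
#'   \item{delimiter}{the species label is the prefix of the gene label before
#'     the first occurrence of `delimiter` (default `"_"`).}
#'   \item{regex}{the species label is the first capture group of `pattern`.}
#'   \item{map}{an explicit lookup: a named character vector
#'     (`names = gene labels`) or a path to a two-column TSV
#'     (gene label, species label; no header).}
#' }
#'
#' @param type One of `"delimiter"`, `"regex"`, `"map"`.
#' @param delimiter Delimiter string for `type = "delimiter"`.
#' @param pattern Regular expression with one capture group for
#'   `type = "regex"`.
#' @param map Named character vector or TSV path for `type = "map"`.
#' @return A `duproot_mapping_rule` object for [map_gene_species()].
#' @examples
#' map_gene_species("Hsap_ENSG0001", mapping_rule("delimiter"))
#' @export
mapping_rule <- function(type = c("delimiter", "regex", "map"),
                         delimiter = "_", pattern = NULL, map = NULL) {
  type <- match.arg(type)
  if (type == "regex" && (is.null(pattern) || !nzchar(pattern))) {
    stop("mapping_rule(type = 'regex') requires 'pattern'", call. = FALSE)
  }
  if (type == "map") {
    if (is.null(map)) stop("mapping_rule(type = 'map') requires 'map'",
                           call. = FALSE)
    if (is.character(map) && is.null(names(map)) && length(map) == 1) {
      tab <- utils::read.delim(map, header = FALSE, colClasses = "character")
      if (ncol(tab) < 2) stop("mapping file must have two columns", call. = FALSE)
      map <- stats::setNames(tab[[2]], tab[[1]])
    }
    if (is.null(names(map))) stop("'map' must be a named vector or a TSV path",
                                  call. = FALSE)
  }
  structure(list(type = type, delimiter = delimiter, pattern = pattern,
                 map = map),
            class = "duproot_mapping_rule")
}

#' Map gene labels to species labels
#'
#' @param labels Character vector of gene labels.
#' @param rule A [mapping_rule()].
#' @return Character vector of species labels. Labels that cannot be mapped
#'   raise an error naming the offending labels and the rule tried.
#' @export
map_gene_species <- function(labels, rule = mapping_rule()) {
  stopifnot(inherits(rule, "duproot_mapping_rule"))
  out <- switch(rule$type,
    delimiter = {
      has <- grepl(rule$delimiter, labels, fixed = TRUE)
      sp <- vapply(strsplit(labels, rule$delimiter, fixed = TRUE),
                   `[[`, "", 1L)
      sp[!has] <- NA_character_
      sp
    },
    regex = {
      m <- regexec(rule$pattern, labels)
      vapply(regmatches(labels, m), function(g)
        if (length(g) >= 2) g[2] else NA_character_, "")
    },
    map = unname(rule$map[labels])
  )
  if (anyNA(out) || any(!nzchar(out))) {
    bad <- labels[is.na(out) | !nzchar(out)]
    stop("cannot map gene label(s) to a species with rule '", rule$type,
         "': ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", call. = FALSE)
  }
  out
}

#' Construct a gene tree bound to a species tree
#'
#' Parses an unrooted gene tree and maps every gene label to a species of
#' `st`. Genes mapping to species absent from the species tree are rejected.
#'
#' @param x A `phylo`, Newick string, or file path.
#' @param st A [species_tree()].
#' @param mapping A [mapping_rule()].
#' @param id Identifier used in event provenance (defaults to the file name
#'   when `x` is a path, else `"gene_tree"`).
#' @return A `duproot_gene_tree`: the unrooted topology plus, per tip, the
#'   index of its species in `st$species`.
#' @export
gene_tree <- function(x, st, mapping = mapping_rule(), id = NULL) {
  stopifnot(inherits(st, "duproot_species_tree"))
  if (is.null(id)) {
    id <- if (is.character(x) && length(x) == 1 && file.exists(x)) {
      tools::file_path_sans_ext(basename(x))
    } else "gene_tree"
  }
  phy <- .as_phylo(x, kind = "gene")
  sp <- map_gene_species(phy$tip.label, mapping)
  idx <- match(sp, st$species)
  if (anyNA(idx)) {
    bad <- unique(sp[is.na(idx)])
    stop("gene tree '", id, "' contains species absent from the species tree: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(phy = phy, species_idx = idx, id = id),
            class = "duproot_gene_tree")
}
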