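# Cross-reference of hybrid parent-of-origin calls against an imprinting
# database: each gene found in both inputs is classified as concordant
# (hybrid origin equals the database's expressed allele), discordant
# (opposite poles), or unresolvable (the database reports biallelic or
# conflicting evidence).

#' Read an imprinting database table
#'
#' Expects a TSV with columns `gene_symbol`, `reported_allele`
#' (`paternal`, `maternal` or `biallelic_or_conflicting`) and
#' `reported_species` (free-text annotation of the species the evidence
#' comes from; carried along, never used for classification). Duplicate
#' gene symbols are an error.
#'
#' @param path TSV file; defaults to the packaged 14-gene fixture
#'   compiled from the geneimprint database entries for the genes with a
#'   single-parent origin in the hybrid.
#' @return data.frame `gene_symbol` (upper-case), `reported_allele`,
#'   `reported_species`.
#' @export
read_imprint_db <- function(path = imprint_fixture_path()) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_symbol", "reported_allele", "reported_species")
                %in% names(db)))
  db$gene_symbol <- toupper(db$gene_symbol)
  dup <- duplicated(db$gene_symbol)
  if (any(dup))
    stop("duplicate gene symbol in imprinting database: ",
         db$gene_symbol[dup][1L], call. = FALSE)
  ok <- c("paternal", "maternal", "biallelic_or_conflicting")
  if (!all(db$reported_allele %in% ok))
    stop("reported_allele must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  db
}

#' Path to the packaged imprinting fixture
#'
#' Fourteen genes expressed in the hybrid from a single parental genome,
#' with the expressed allele reported for them in the geneimprint
#' database (including two predicted entries, treated like experimental
#' ones).
#'
#' @return file path of the TSV inside the installed package.
#' @export
imprint_fixture_path <- function() {
  system.file("extdata", "imprint_db_crossref.tsv", package = "hybridscope",
              mustWork = TRUE)
}

#' Hybrid parent-of-origin calls packaged with the imprinting fixture
#'
#' @return data.frame `gene_symbol`, `origin` (`paternal`/`maternal`) of
#'   the hybrid's observed transcript origin for the fixture genes.
#' @export
imprint_fixture_origins <- function() {
  f <- system.file("extdata", "imprint_origin_calls.tsv",
                   package = "hybridscope", mustWork = TRUE)
  x <- utils::read.delim(f, stringsAsFactors = FALSE)
  x$gene_symbol <- toupper(x$gene_symbol)
  x
}

#' Cross-reference origin calls against an imprinting database
#'
#' Matches genes present in both inputs and classifies each: concordant
#' when the hybrid's parent of origin equals the database's reported
#' expressed allele, discordant when the two are opposite poles, and
#' unresolvable when the database reports biallelic or conflicting
#' evidence (such genes are never counted as discordant).
#'
#' @param origin_calls data.frame `gene_symbol`, `origin`
#'   (`"paternal"`/`"maternal"`), or a named character vector of origins.
#' @param database data.frame from [read_imprint_db()].
#' @return list of class `imprint_crossref`: `matched` (per-gene table
#'   with a `concordance` column), `n_matched`, `n_concordant`,
#'   `n_discordant`, `n_unresolvable`.
#' @export
crossref_imprint <- function(origin_calls, database = read_imprint_db()) {
  if (!is.data.frame(origin_calls))
    origin_calls <- data.frame(gene_symbol = names(origin_calls),
                               origin = unname(origin_calls),
                               stringsAsFactors = FALSE)
  stopifnot(all(c("gene_symbol", "origin") %in% names(origin_calls)),
            all(origin_calls$origin %in% c("paternal", "maternal")))
  origin_calls$gene_symbol <- toupper(origin_calls$gene_symbol)
  if (any(duplicated(origin_calls$gene_symbol)))
    stop("duplicate gene symbol among origin calls", call. = FALSE)
  dup <- duplicated(toupper(database$gene_symbol))
  if (any(dup))
    stop("duplicate gene symbol in imprinting database: ",
         database$gene_symbol[dup][1L], call. = FALSE)
  m <- merge(origin_calls, database, by = "gene_symbol")
  m$concordance <- ifelse(
    m$reported_allele == "biallelic_or_conflicting", "unresolvable",
    ifelse(m$origin == m$reported_allele, "concordant", "discordant"))
  m <- m[order(m$gene_symbol), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(matched = m,
                 n_matched = nrow(m),
                 n_concordant = sum(m$concordance == "concordant"),
                 n_discordant = sum(m$concordance == "discordant"),
                 n_unresolvable = sum(m$concordance == "unresolvable")),
            class = "imprint_crossref")
}

#' @export
print.imprint_crossref <- function(x, ...) {
  cat("Imprinting cross-reference:", x$n_matched, "matched genes\n")
  cat("  concordant:  ", x$n_concordant, "\n")
  cat("  discordant:  ", x$n_discordant, "\n")
  cat("  unresolvable:", x$n_unresolvable, "\n")
  invisible(x)
}
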