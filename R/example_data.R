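#' Bundled example resources
#'
#' Small worked-example resources shipped with the package: a toy lexicon of
#' heart-failure and oncology phenotype concepts (each target concept
#' accompanied by distractor concepts sharing surface tokens, so candidate
#' selection is non-trivial), the clinical abbreviation dictionary, and the
#' qualifier-word synonym resource. They make every example in the
#' documentation runnable offline and are the fixtures used by the package's
#' own test-suite; real deployments substitute a filtered UMLS-derived
#' lexicon via [load_rrf_lexicon()] or [load_tsv_lexicon()].
#'
#' @return `example_lexicon()` a `pheno_lexicon`; `example_abbreviations()` a
#'   `pheno_abbreviations` dictionary; `example_synonym_resource()` a
#'   `pheno_synonym_resource`.
#' @export
example_lexicon <- function() {
  load_tsv_lexicon(pkg_extdata("example_lexicon.tsv"))
}

#' @rdname example_lexicon
#' @export
example_abbreviations <- function() {
  read_abbreviations(pkg_extdata("abbreviations.tsv"))
}

#' @rdname example_lexicon
#' @export
example_synonym_resource <- function() {
  read_synonym_resource(pkg_extdata("synonym_resource.tsv"))
}
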