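# Genetic-environment classification of ldc genes. In E. coli the
# acid-inducible ldcI sits in an operon with cadB (a lysine-cadaverine
# antiporter), while the biosynthetic ldcC lies between accA and yaeR;
# those two configurations are the classification rules, applied to
# annotation names only (no homology search).

#' Default gene-name synonym lists for the context rules
#'
#' Case-insensitive exact-match synonym sets for the diagnostic
#' neighbors: the cadB-family antiporter, accA and yaeR.
#'
#' @return Named list of character vectors.
#' @export
context_synonyms <- function() {
  list(cadB = c("cadB", "ldcB", "antiporter"),
       accA = c("accA"),
       yaeR = c("yaeR"))
}

# stated annotation -> expected group call (NA = no expectation)
stated_to_call <- function(stated) {
  map <- c(ldcI = "ldcI-like", cadA = "ldcI-like", ldcC = "ldcC-like")
  out <- unname(map[stated])
  out
}

#' Classify ldc genes by their genetic environment
#'
#' Rule 1 (ldcI-like): a cadB-family antiporter gene is an immediate
#' neighbor and is flagged as belonging to the same operon. Rule 2
#' (ldcC-like): the gene is flanked by an accA-family gene on one side
#' and a yaeR-family gene on the other (either order). If both rules
#' fire the call is `"unknown"` with evidence `"ambiguous"`; if neither
#' fires (including an empty neighborhood) the call is `"unknown"` with
#' evidence `"no-context"`.
#'
#' @param records Neighborhood table (data.frame with columns `gene_id`,
#'   `taxon`, `strand`, `upstream_gene`, `downstream_gene`,
#'   `same_operon_flag`, `stated_annotation`), e.g. from
#'   [gen_neighborhood_table()] or [read_neighborhood_tsv()].
#' @param synonyms Gene-name synonym lists; see [context_synonyms()].
#' @return A `context_calls` data.frame: `gene_id`, `taxon`, `call`,
#'   `evidence`, `stated_annotation`, `conflict_with_stated`.
#' @export
classify_by_context <- function(records, synonyms = context_synonyms()) {
  needed <- c("gene_id", "taxon", "upstream_gene", "downstream_gene",
              "same_operon_flag", "stated_annotation")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0)
    stop("neighborhood table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  low <- function(x) tolower(ifelse(is.na(x), "", x))
  syn <- lapply(synonyms, tolower)
  n <- nrow(records)
  call <- character(n); evidence <- character(n)
  for (i in seq_len(n)) {
    up <- low(records$upstream_gene[i])
    down <- low(records$downstream_gene[i])
    flanks <- c(up, down)
    has_any <- any(nzchar(flanks))
    r1 <- any(flanks %in% syn$cadB) &&
      isTRUE(as.logical(records$same_operon_flag[i]))
    r2 <- any(flanks %in% syn$accA) && any(flanks %in% syn$yaeR)
    if (!has_any) { call[i] <- "unknown"; evidence[i] <- "no-context" }
    else if (r1 && r2) { call[i] <- "unknown"; evidence[i] <- "ambiguous" }
    else if (r1) { call[i] <- "ldcI-like"; evidence[i] <- "cadB-operon" }
    else if (r2) { call[i] <- "ldcC-like"; evidence[i] <- "accA-yaeR-flanks" }
    else { call[i] <- "unknown"; evidence[i] <- "no-context" }
  }
  expected <- stated_to_call(records$stated_annotation)
  conflict <- !is.na(expected) & call != "unknown" & call != expected
  structure(data.frame(gene_id = records$gene_id,
                       taxon = records$taxon,
                       call = call, evidence = evidence,
                       stated_annotation = records$stated_annotation,
                       conflict_with_stated = conflict,
                       stringsAsFactors = FALSE),
            class = c("context_calls", "data.frame"))
}

#' Audit stated annotations against the genetic environment
#'
#' Runs [classify_by_context()] on every record, flags conflicts between
#' the stated annotation and the context call, and attaches a
#' stated-by-called contingency table.
#'
#' @inheritParams classify_by_context
#' @return A `context_calls` data.frame with a `summary` attribute (the
#'   stated x called count table).
#' @export
audit_annotations <- function(records, synonyms = context_synonyms()) {
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene_id in neighborhood table", call. = FALSE)
  calls <- classify_by_context(records, synonyms)
  attr(calls, "summary") <- table(stated = calls$stated_annotation,
                                  called = calls$call)
  calls
}

#' @export
print.context_calls <- function(x, ...) {
  cat(sprintf("Context calls for %d genes:\n", nrow(x)))
  print(table(x$call))
  nc <- sum(x$conflict_with_stated)
  if (nc > 0) {
    cat(sprintf("%d annotation conflict(s):\n", nc))
    print.data.frame(x[x$conflict_with_stated,
                       c("gene_id", "stated_annotation", "call")],
                     row.names = FALSE)
  } else cat("no annotation conflicts\n")
  invisible(x)
}

#' Read / write the neighborhood TSV format
#'
#' Columns: `gene_id`, `taxon`, `strand`, `upstream_gene`,
#' `downstream_gene`, `same_operon_flag`, `stated_annotation`.
#'
#' @param file Path to a TSV file.
#' @return `read_neighborhood_tsv`: the table as a data.frame.
#' @export
read_neighborhood_tsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("gene_id", "taxon", "strand", "upstream_gene",
              "downstream_gene", "same_operon_flag", "stated_annotation")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("neighborhood TSV lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab$same_operon_flag <- as.logical(tab$same_operon_flag)
  tab
}

#' @rdname read_neighborhood_tsv
#' @param tab Neighborhood table.
#' @export
write_neighborhood_tsv <- function(tab, file) {
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
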