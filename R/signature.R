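#' Named gene set with provenance
#'
#' @param name set name.
#' @param genes character vector (deduplicated, sorted for stable output).
#' @param provenance character vector recording the contrasts/thresholds
#'   the set came from.
#' @return a `gene_set` list.
#' @export
gene_set <- function(name, genes, provenance = character()) {
  structure(list(name = name, genes = sort(unique(as.character(genes))),
                 provenance = provenance), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Three-way intersection of upregulated gene sets
#'
#' The first derivation step of the projected senescence signature:
#' genes upregulated in projected-young tumor cells AND in tumor vs normal
#' cells AND in bulk tumor vs normal tissue. Commutative and associative
#' in its arguments; provenance is concatenated.
#'
#' @param a,b,c [gene_set]s (a warning is raised for empty inputs).
#' @param name name for the result.
#' @return a [gene_set] holding the exact three-way intersection.
#' @export
intersect_signatures <- function(a, b, c, name = "common_up") {
  sets <- list(a, b, c)
  if (any(vapply(sets, function(s) length(s$genes) == 0, logical(1)))) {
    warn("One or more input gene sets are empty; the intersection will be empty.")
  }
  genes <- Reduce(intersect, lapply(sets, `[[`, "genes"))
  gene_set(name, genes,
           provenance = unlist(lapply(sets, function(s) c(s$name, s$provenance))))
}

#' Cross-species filter against young-up aging genes
#'
#' Retains candidate genes having at least one ortholog among the
#' young-upregulated genes of the aging atlas (derived with the aging
#' thresholds: log2 fold change above 0.1, adjusted p below 0.05). Output
#' stays in the human namespace; with a many-to-many map a single passing
#' ortholog suffices.
#'
#' @param candidates a [gene_set] in the human namespace.
#' @param aging_young_up a [gene_set] in the ortholog namespace.
#' @param map an [ortholog_map()] tibble.
#' @param name name for the result.
#' @return a [gene_set]; empty (with a warning) when the map is empty.
#' @export
cross_species_filter <- function(candidates, aging_young_up, map,
                                 name = "psag") {
  if (!nrow(map)) {
    warn("Empty ortholog map; returning an empty gene set.")
    return(gene_set(name, character(),
                    provenance = c(candidates$name, "cross_species_filter(empty map)")))
  }
  hits <- map$human_symbol[map$ortholog_symbol %in% aging_young_up$genes]
  gene_set(name, intersect(candidates$genes, hits),
           provenance = c(candidates$name, candidates$provenance,
                          aging_young_up$name,
                          "cross_species_filter(>=1 ortholog young-up)"))
}

#' Derive the projected senescence-associated signature end to end
#'
#' Convenience wrapper: three-way intersection of the upregulated contrast
#' sets, then the cross-species filter against the aging atlas.
#'
#' @param young_vs_old,tumor_vs_normal,bulk_tumor_vs_normal upregulated
#'   [gene_set]s from the three human contrasts.
#' @param aging_young_up young-up [gene_set] from the aging atlas
#'   (ortholog namespace).
#' @param map an [ortholog_map()].
#' @return a [gene_set] named `"psag"`.
#' @export
derive_psag <- function(young_vs_old, tumor_vs_normal, bulk_tumor_vs_normal,
                        aging_young_up, map) {
  common <- intersect_signatures(young_vs_old, tumor_vs_normal,
                                 bulk_tumor_vs_normal, name = "common_up")
  cross_species_filter(common, aging_young_up, map, name = "psag")
}
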