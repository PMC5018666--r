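#' Assign a WRKY protein to its main group from its domain inventory
#'
#' Structural rules: two (or more) WRKY domains make group I (domains
#' labelled `-N`/`-C` in order); a single domain with a C2HC finger makes
#' group III; a single domain with a C2H2 (or shortened variant) finger makes
#' group II, with the subgroup left for reference-guided placement; a single
#' domain carrying two or more consecutive zinc fingers is treated as group I
#' (a two-domain gene that lost one heptapeptide); a single incomplete domain
#' is provisionally group II pending reference placement.
#'
#' @param domains Tibble of domains for one protein (from [scan_protein()]).
#' @return One-row tibble: `protein_id`, `group` (`"I"`, `"II"`, `"III"`),
#'   `subgroup_pending` (logical), `evidence`, `domain_labels` (list column,
#'   `-N`/`-C` suffixed for group I).
#' @export
assign_group <- function(domains) {
  if (nrow(domains) == 0) {
    wrky_abort("no WRKY domain detected: protein is not a family member")
  }
  id <- domains$protein_id[1]
  n <- nrow(domains)
  if (n >= 2) {
    labels <- paste0(id, c("-N", "-C", paste0("-D", seq_len(max(0, n - 2)) + 2L))[seq_len(n)])
    return(tibble(
      protein_id = id, group = "I", subgroup_pending = FALSE,
      evidence = "structural_rule", domain_labels = list(labels)
    ))
  }
  d <- domains[1, ]
  if (isTRUE(d$n_fingers >= 2)) {
    group <- "I"
    pending <- FALSE
  } else if (identical(d$finger_type, "C2HC")) {
    group <- "III"
    pending <- FALSE
  } else if (d$finger_type %in% c("C2H2", "variant-C2H2")) {
    group <- "II"
    pending <- TRUE
  } else { # incomplete finger: keep the gene, place by nearest reference
    group <- "II"
    pending <- TRUE
  }
  tibble(
    protein_id = id, group = group, subgroup_pending = pending,
    evidence = if (d$complete) "structural_rule" else "incomplete_finger",
    domain_labels = list(id)
  )
}

#' Reference-guided subgroup placement of a WRKY domain
#'
#' @param query_seq Amino-acid string of the query WRKY domain.
#' @param references Tibble with columns `label` (e.g. `IIa`..`IIe`, `I-N`,
#'   `I-C`, `III`) and `sequence`; at least one exemplar per subgroup
#'   IIa-IIe is expected.
#' @param method `"tree"` (default): build a neighbor-joining tree of the
#'   query plus references from a progressive alignment and take the
#'   majority label of the smallest clade next to the query that contains a
#'   reference; `"nearest"`: label of the reference at smallest p-distance
#'   (computed on the pairwise global alignment, gap columns excluded).
#'   Tree ties fall back to `"nearest"`; nearest ties are broken by
#'   first-in-panel order and flagged.
#' @return One-row tibble: `subgroup`, `method_used`, `tie`.
#' @export
assign_subgroup <- function(query_seq, references, method = c("tree", "nearest")) {
  method <- match.arg(method)
  if (is.null(references) || nrow(references) == 0) {
    wrky_abort("empty reference panel")
  }
  need <- paste0("II", letters[1:5])
  if (!all(need %in% references$label)) {
    missing <- setdiff(need, references$label)
    wrky_abort(paste0("reference panel lacks subgroup exemplar(s): ",
                      paste(missing, collapse = ", ")))
  }
  nearest <- function() {
    d <- map_dbl(references$sequence, function(r) pairwise_p_distance(query_seq, r))
    best <- which(d == min(d))
    tibble(
      subgroup = references$label[best[1]], method_used = "nearest",
      tie = length(unique(references$label[best])) > 1
    )
  }
  if (method == "nearest" || nrow(references) < 2) return(nearest())

  labels <- c("query", paste0("ref", seq_len(nrow(references))))
  msa <- progressive_msa(c(query_seq, references$sequence), labels = labels)
  dm <- p_distance(msa)
  tree <- neighbor_joining(dm)
  rooted <- ape::root(tree, outgroup = "query", resolve.root = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root_node, 2]
  query_tip <- which(rooted$tip.label == "query")
  sib <- kids[kids != query_tip]
  # candidate clades: the subtrees hanging off the query's attachment node
  cands <- if (all(sib <= length(rooted$tip.label))) sib else {
    rooted$edge[rooted$edge[, 1] == sib, 2]
  }
  tips_of <- function(node) {
    unlist(phangorn::Descendants(rooted, node, type = "tips"))
  }
  cand_tips <- map(cands, tips_of)
  sizes <- lengths(cand_tips)
  for (k in order(sizes)) {
    refs_in <- setdiff(rooted$tip.label[cand_tips[[k]]], "query")
    if (length(refs_in) == 0) next
    lab <- references$label[match(refs_in, labels[-1])]
    tab <- sort(table(lab), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(mutate(nearest(), tie = TRUE))
    return(tibble(subgroup = names(tab)[1], method_used = "tree", tie = FALSE))
  }
  nearest()
}

#' Classify a scanned proteome into WRKY groups and subgroups
#'
#' Applies [assign_group()] per protein, then places group II members (and
#' proteins whose only domain lacks a recognisable finger) with
#' [assign_subgroup()] against a labelled reference panel.  Proteins whose
#' nearest reference is a group I or III exemplar are reassigned to that
#' group (this is how fingerless domains inherit a placement).
#'
#' @param domains Domain tibble from [scan_proteins()].
#' @param proteins Tibble with `id` and `sequence` (domain sequences are cut
#'   from it).
#' @param references Reference panel tibble (`label`, `sequence`), e.g. from
#'   [generate_reference_panel()]; `NULL` leaves subgroups unassigned.
#' @param method Passed to [assign_subgroup()].
#' @return Tibble: `protein_id`, `group` (one of `I`, `IIa`..`IIe`, `III`,
#'   `unclassified`), `subgroup_evidence`, `tie`, `domain_labels`.
#' @export
classify_proteins <- function(domains, proteins, references = NULL,
                              method = c("tree", "nearest")) {
  method <- match.arg(method)
  ids <- unique(domains$protein_id)
  rows <- map(ids, function(id) {
    dd <- domains[domains$protein_id == id, ]
    g <- assign_group(dd)
    if (g$group != "II") {
      return(tibble(
        protein_id = id, group = g$group, subgroup_evidence = g$evidence,
        tie = FALSE, domain_labels = g$domain_labels
      ))
    }
    if (is.null(references)) {
      return(tibble(
        protein_id = id, group = "unclassified",
        subgroup_evidence = "no_reference_panel", tie = FALSE,
        domain_labels = g$domain_labels
      ))
    }
    seq <- proteins$sequence[match(id, proteins$id)]
    dseq <- stringr::str_sub(seq, dd$domain_start[1], dd$domain_end[1])
    sg <- assign_subgroup(dseq, references, method = method)
    group <- if (sg$subgroup %in% c("I-N", "I-C")) "I"
      else if (sg$subgroup == "III") "III"
      else sg$subgroup
    tibble(
      protein_id = id, group = group,
      subgroup_evidence = paste0("reference_", sg$method_used),
      tie = sg$tie, domain_labels = g$domain_labels
    )
  })
  bind_rows(rows)
}
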