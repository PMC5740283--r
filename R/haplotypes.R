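# sequence compatibility under the N-matches-anything rule ('-' is a real symbol)
seq_compatible <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  if (length(va) != length(vb)) abort("sequence length mismatch")
  ok <- va == vb | va == "N" | vb == "N"
  all(ok)
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical at all unambiguous positions merge (`N` matches
#' anything). Members are processed in order of increasing ambiguity (fewest
#' `N`s first, ties broken by id sort) and merged into the first existing
#' haplotype whose representative they are compatible with; representatives
#' are therefore pairwise incompatible and collapsing is idempotent. The
#' representative of a haplotype is its member with fewest `N`s.
#'
#' @param seqs tibble with columns `id`, `seq` (aligned, equal length).
#' @param species optional named character vector (id -> species label) to
#'   carry through; a haplotype's species set is the union over members.
#' @return tibble of class `haplotype_set`: columns `haplotype`, `seq`
#'   (representative), `multiplicity`, `members` (list column),
#'   `species` (list column of labels, possibly empty).
#' @export
collapse_haplotypes <- function(seqs, species = NULL) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (length(unique(nchar(seqs$seq))) > 1) abort("sequence length mismatch")
  n_amb <- vapply(strsplit(seqs$seq, ""), function(v) sum(v == "N"), 0L)
  ord <- order(n_amb, seqs$id)
  reps <- character(0)
  members <- list()
  for (i in ord) {
    hit <- which(vapply(reps, seq_compatible, TRUE, b = seqs$seq[i]))
    if (length(hit)) {
      j <- hit[1]
      members[[j]] <- c(members[[j]], seqs$id[i])
    } else {
      reps <- c(reps, seqs$seq[i])
      members[[length(reps)]] <- seqs$id[i]
    }
  }
  sp <- lapply(members, function(m)
    if (is.null(species)) character(0) else sort(unique(unname(species[m]))))
  tbl <- tibble::tibble(
    haplotype = sprintf("H%03d", seq_along(reps)),
    seq = reps,
    multiplicity = lengths(members),
    members = members,
    species = sp
  )
  class(tbl) <- c("haplotype_set", class(tbl))
  tbl
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds a p-distance matrix (pairwise proportion of differing unambiguous
#' sites), joins by the Saitou-Nei criterion, roots on the outgroup, and
#' attaches site-resampling bootstrap support (percent of replicates
#' containing each bipartition).
#'
#' @param seqs tibble (id, seq), aligned.
#' @param outgroup character ids used to root the tree.
#' @param bootstrap number of bootstrap replicates (0 to skip).
#' @return list of class `nj_result`: `tree` (rooted `phylo` with node
#'   labels = support), `support` (numeric per internal node of the unrooted
#'   tree), `newick` (string).
#' @export
build_nj_tree <- function(seqs, outgroup = character(0), bootstrap = 1000L) {
  if (nrow(seqs) < 3) abort("need at least 3 sequences")
  if (length(outgroup) && !all(outgroup %in% seqs$id)) abort("outgroup ids absent")
  dna <- seq_tbl_to_dnabin(seqs)
  d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  if (any(is.na(d) | is.nan(d))) abort("a sequence pair shares no comparable sites")
  tree <- ape::nj(d)
  support <- NULL
  if (bootstrap > 0) {
    bp <- ape::boot.phylo(tree, dna, function(x)
      ape::nj(ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE)),
      B = bootstrap, quiet = TRUE, rooted = FALSE)
    support <- 100 * bp / bootstrap
    tree$node.label <- round(support, 1)
  }
  if (length(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  structure(list(tree = tree, support = support,
                 newick = ape::write.tree(tree)),
            class = "nj_result")
}

seq_tbl_to_dnabin <- function(seqs) {
  m <- do.call(rbind, strsplit(tolower(seqs$seq), ""))
  rownames(m) <- seqs$id
  ape::as.DNAbin(m)
}

#' Assign haplotypes to species by clade membership
#'
#' Each query is assigned the species of the smallest clade that contains the
#' query and at least one reference haplotype: if all references in that
#' clade belong to one species the query takes that species, otherwise it is
#' `AMBIGUOUS`.
#'
#' @param haps a `haplotype_set` (queries are haplotypes without a species).
#' @param references tibble (haplotype, species) of species-labelled tips.
#' @param tree rooted `phylo` containing all query and reference tips (e.g.
#'   from [build_nj_tree()]).
#' @return `haps` with an `assignment` column
#'   (species / `"AMBIGUOUS"`).
#' @export
assign_haplotype_species <- function(haps, references, tree) {
  if (inherits(tree, "nj_result")) tree <- tree$tree
  if (!all(haps$haplotype %in% tree$tip.label)) {
    abort(paste("query haplotypes absent from tree:",
                paste(setdiff(haps$haplotype, tree$tip.label), collapse = ", ")))
  }
  if (!all(references$haplotype %in% tree$tip.label)) {
    abort("reference haplotypes absent from tree")
  }
  ref_sp <- setNames(references$species, references$haplotype)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  tips_below <- clade_tips(tree)
  assign_one <- function(h) {
    node <- match(h, tree$tip.label)
    repeat {
      node <- parent[node]
      tips <- tips_below[[node - n_tip]]
      refs <- intersect(tips, references$haplotype)
      if (length(refs)) {
        sp <- unique(ref_sp[refs])
        return(if (length(sp) == 1) unname(sp) else "AMBIGUOUS")
      }
      if (node == root) return("AMBIGUOUS")
    }
  }
  haps$assignment <- vapply(haps$haplotype, assign_one, "", USE.NAMES = FALSE)
  haps
}

# list of tip labels under each internal node (index 1 = first internal node)
clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- vector("list", tree$Nnode)
  recurse <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    cached <- out[[node - n_tip]]
    if (!is.null(cached)) return(cached)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    tips <- unlist(lapply(kids, recurse))
    out[[node - n_tip]] <<- tips
    tips
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  recurse(root)
  out
}

#' Allocate a short internal fragment to a species-diagnostic mtDNA type
#'
#' Full-length assigned haplotypes are trimmed to the fragment's window and
#' re-collapsed (carrying species labels); the fragment is assigned if and
#' only if every trimmed haplotype it matches belongs to a single species.
#'
#' @param fragment nucleotide string of the fragment (length = window width).
#' @param haps a `haplotype_set` with an `assignment` column (full length).
#' @param window integer c(start, end), 1-based inclusive, within the full
#'   alignment.
#' @return single species label, `"AMBIGUOUS"` (matches >1 species), or
#'   `"UNASSIGNED"` (matches nothing).
#' @export
assign_internal_fragment <- function(fragment, haps, window) {
  full_len <- nchar(haps$seq[1])
  if (window[1] < 1 || window[2] > full_len || window[1] > window[2]) {
    abort("window outside the full-length alignment")
  }
  if (nchar(fragment) != window[2] - window[1] + 1) {
    abort("fragment length does not match the window")
  }
  if (!"assignment" %in% names(haps)) abort("haplotypes must be species-assigned first")
  trimmed <- tibble::tibble(
    id = haps$haplotype,
    seq = substr(haps$seq, window[1], window[2])
  )
  sp <- setNames(haps$assignment, haps$haplotype)
  re <- collapse_haplotypes(trimmed, species = sp)
  hit <- vapply(re$seq, seq_compatible, TRUE, b = toupper(fragment))
  if (!any(hit)) return("UNASSIGNED")
  species <- sort(unique(unlist(re$species[hit])))
  species <- setdiff(species, c("AMBIGUOUS", "UNASSIGNED"))
  if (length(species) == 1) species else "AMBIGUOUS"
}
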