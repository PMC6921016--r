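# Fully in-silico test world with the statistical structure the method
# assumes: complexes composed of planted sub-complexes whose members share
# signature GO terms and are densely wired by direct contacts, an observed
# physical interactome equal to the true contact network, and homolog
# annotations derived from the target annotations by dropout plus noise-term
# insertion. Signature sharing makes direct contacts learnable from the pair
# features; sparse cross-group wiring creates both negative-sampling pools
# (connected at length >= 2, and disconnected = no-path).

#' Configuration of the synthetic world
#'
#' Defaults describe a small human-complexome-like benchmark: many small
#' complexes and few large ones (truncated geometric size distribution),
#' roughly 60% of complexes fully connected (every subunit pair in direct
#' contact, exercising the functional-clustering branch) and the rest
#' partially connected with dense within-group and sparse between-group
#' wiring. Planted sub-complex count grows with complex size
#' (`max(1, min(3, N %/% 3))`, so each group has >= 3 members).
#'
#' @param n_complexes Number of complexes.
#' @param size_min,size_max,size_p Complex sizes are
#'   `size_min + rgeom(size_p)` truncated at `size_max`.
#' @param frac_full Fraction of complexes generated fully connected.
#' @param group_size Target functional-group size in fully connected
#'   complexes; a complex with N subunits gets
#'   `max(1, min(4, N %/% group_size))` groups.
#' @param core_frac Fraction of a partially connected complex's subunits
#'   forming its densely wired core (the planted sub-complex); the remaining
#'   subunits are sparse attachments.
#' @param p_in,p_out Direct-contact probability within the core / elsewhere
#'   in partially connected complexes.
#' @param sig_per_group Signature GO terms shared by all members of a
#'   functional group or core.
#' @param bg_terms_per_gene Background GO terms drawn per gene.
#' @param bg_pool Size of the background term pool.
#' @param n_internal Internal (non-leaf) DAG terms below the three roots.
#' @param homolog_dropout Probability that a target term is missing from the
#'   homolog set.
#' @param homolog_noise Probability that one random pool term is inserted
#'   into a gene's homolog set.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_complexes = 60L, size_min = 3L, size_max = 40L,
                             size_p = 0.12, frac_full = 0.6,
                             group_size = 4L, core_frac = 0.6,
                             p_in = 0.9, p_out = 0.05,
                             sig_per_group = 2L,
                             bg_terms_per_gene = 3L, bg_pool = 300L,
                             n_internal = 30L,
                             homolog_dropout = 0.2, homolog_noise = 0.2) {
  structure(as.list(environment()), class = "synthetic_config")
}

random_dag <- function(n_leaves, n_internal) {
  roots <- c("GO:0008150", "GO:0003674", "GO:0005575")
  ns <- c("biological_process", "molecular_function", "cellular_component")
  internal <- sprintf("GO:1%06d", seq_len(n_internal))
  leaves <- sprintf("GO:2%06d", seq_len(n_leaves))
  child <- character(); parent <- character(); relation <- character()
  ns_of <- stats::setNames(ns, roots)
  pick_rel <- function(k) sample(c("is_a", "part_of"), k, TRUE, prob = c(0.8, 0.2))
  for (i in seq_len(n_internal)) {
    # parents come from roots or earlier internal terms: acyclic by layering
    pool <- c(roots, internal[seq_len(i - 1L)])
    pa <- sample(pool, min(length(pool), sample(1:2, 1L)))
    child <- c(child, rep(internal[[i]], length(pa)))
    parent <- c(parent, pa)
    relation <- c(relation, pick_rel(length(pa)))
    ns_of[internal[[i]]] <- ns_of[[pa[[1L]]]]
  }
  for (i in seq_len(n_leaves)) {
    pa <- sample(internal, sample(1:2, 1L))
    child <- c(child, rep(leaves[[i]], length(pa)))
    parent <- c(parent, pa)
    relation <- c(relation, pick_rel(length(pa)))
    ns_of[leaves[[i]]] <- ns_of[[pa[[1L]]]]
  }
  list(dag = go_dag(c(roots, internal, leaves),
                    data.frame(child = child, parent = parent,
                               relation = relation)),
       leaves = leaves,
       namespace = ns_of)
}

#' Generate a synthetic world
#'
#' All randomness flows from `seed`; per-stage sub-seeds are derived by fixed
#' offsets, so the same seed always yields the identical world.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Object of class `synthetic_world` with elements `dag`, `genes`,
#'   `target`, `homolog`, `complexes`, `groups` (planted sub-complexes, a
#'   named list of lists of gene vectors), `contacts` (true direct-contact
#'   network), `interactome` (observed physical network), `full_complexes`
#'   (character vector of complexes generated fully connected), `config`,
#'   `seed`.
#' @export
generate_world <- function(config = synthetic_config(), seed = 1L) {
  withr_seed(seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  sizes <- pmin(cfg$size_min + stats::rgeom(cfg$n_complexes, cfg$size_p),
                cfg$size_max)
  n_genes <- sum(sizes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  cids <- sprintf("CPX%03d", seq_len(cfg$n_complexes))
  is_full <- seq_len(cfg$n_complexes) <= round(cfg$frac_full * cfg$n_complexes)
  is_full <- sample(is_full)   # random placement across sizes

  # leaf terms: group/core signatures + background pool
  n_groups_of <- function(N) max(1L, min(4L, N %/% cfg$group_size))
  n_groups <- ifelse(is_full, vapply(sizes, n_groups_of, integer(1)), 1L)
  n_sig <- sum(n_groups) * cfg$sig_per_group
  dag_parts <- random_dag(n_sig + cfg$bg_pool, cfg$n_internal)
  leaves <- dag_parts$leaves
  sig_terms <- leaves[seq_len(n_sig)]
  bg_terms <- leaves[n_sig + seq_len(cfg$bg_pool)]

  complexes <- list(); groups <- list()
  contacts_from <- character(); contacts_to <- character()
  target <- stats::setNames(vector("list", n_genes), genes)
  offset <- 0L; sig_ptr <- 0L
  take_sig <- function(k) {
    out <- sig_terms[sig_ptr + seq_len(k)]
    sig_ptr <<- sig_ptr + k
    out
  }
  for (c_i in seq_len(cfg$n_complexes)) {
    N <- sizes[[c_i]]
    members <- genes[offset + seq_len(N)]
    offset <- offset + N
    complexes[[cids[[c_i]]]] <- members
    if (is_full[[c_i]]) {
      # fully connected complex: every pair in contact; planted substructure
      # is functional (annotation-level groups)
      g <- n_groups[[c_i]]
      grp <- split(members, sort(rep_len(seq_len(g), N)))
      names(grp) <- sprintf("%s.g%d", cids[[c_i]], seq_len(g))
      groups[[cids[[c_i]]]] <- grp
      for (gi in seq_along(grp)) {
        gsig <- take_sig(cfg$sig_per_group)
        for (gene in grp[[gi]])
          target[[gene]] <- c(gsig, sample(bg_terms, cfg$bg_terms_per_gene))
      }
      prs <- utils::combn(members, 2L)
      drawn <- rep(TRUE, ncol(prs))
    } else {
      # partially connected complex: a densely wired, signature-annotated
      # core (the planted sub-complex) plus sparsely attached subunits
      n_core <- max(2L, round(cfg$core_frac * N))
      core <- members[seq_len(n_core)]
      grp <- list(core)
      names(grp) <- sprintf("%s.core", cids[[c_i]])
      groups[[cids[[c_i]]]] <- grp
      gsig <- take_sig(cfg$sig_per_group)
      for (gene in core)
        target[[gene]] <- c(gsig, sample(bg_terms, cfg$bg_terms_per_gene))
      for (gene in setdiff(members, core))
        target[[gene]] <- sample(bg_terms, cfg$bg_terms_per_gene)
      prs <- utils::combn(members, 2L)
      in_core <- prs[1L, ] %in% core & prs[2L, ] %in% core
      drawn <- stats::runif(ncol(prs)) <=
        ifelse(in_core, cfg$p_in, cfg$p_out)
    }
    contacts_from <- c(contacts_from, prs[1L, drawn])
    contacts_to <- c(contacts_to, prs[2L, drawn])
  }

  homolog <- lapply(target, function(tt) {
    kept <- tt[stats::runif(length(tt)) > cfg$homolog_dropout]
    if (stats::runif(1L) < cfg$homolog_noise)
      kept <- c(kept, sample(bg_terms, 1L))
    kept
  })

  contacts <- gene_network(
    data.frame(from = contacts_from, to = contacts_to, weight = 1),
    vertices = genes)
  world <- structure(list(
    dag = dag_parts$dag,
    genes = genes,
    target = annotation_set(target, "target"),
    homolog = annotation_set(homolog, "homolog"),
    complexes = complex_set(complexes),
    groups = groups,
    contacts = contacts,
    interactome = contacts,
    full_complexes = cids[is_full],
    config = cfg), class = "synthetic_world")

  # the sampler needs indirect pairs to draw from; degenerate configs can
  # leave one pool empty (e.g. p_in = 1 yields clique components and hence no
  # length >= 2 paths), which the sampler tolerates with a deficit warning
  cc <- cocomplex_pairs(world$complexes)
  cls <- path_class(cc, world$interactome)
  n_np <- sum(cls == "no-path"); n_nl <- sum(cls == "no-less-than-two")
  if (n_np == 0L && n_nl == 0L)
    stop("synthetic config yields an empty negative pool ",
         "(no indirect co-complexed pairs at all)")
  if (n_np == 0L || n_nl == 0L)
    warning("one negative pool is empty (no-path: ", n_np,
            ", no-less-than-two: ", n_nl, ")")
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", length(x$genes), "genes,",
      length(x$complexes), "complexes (", length(x$full_complexes),
      "fully connected ),", nrow(x$contacts$edges), "true contacts,",
      length(x$dag$terms), "GO terms\n")
  invisible(x)
}

#' Gold-standard tables of a synthetic world
#'
#' @param world A `synthetic_world`.
#' @return List: `pairs` (every co-complexed pair with `label` +1 for a true
#'   direct contact / -1 otherwise, and `provenance` from [path_class()] on
#'   the interactome) and `subcomplexes` (named list of planted sub-complex
#'   gene vectors across all complexes).
#' @export
truth_tables <- function(world) {
  cc <- cocomplex_pairs(world$complexes)
  keys <- pair_key(cc$geneA, cc$geneB)
  direct <- keys %in% pair_key(world$contacts$edges$from,
                               world$contacts$edges$to)
  cc$label <- ifelse(direct, 1L, -1L)
  cc$provenance <- path_class(cc, world$interactome)
  refs <- do.call(c, unname(world$groups))
  list(pairs = cc, subcomplexes = refs)
}

#' Write a synthetic world to plain-text files
#'
#' Writes `ontology.obo`, `target.tsv`, `homolog.tsv` (two-column
#' annotations), `interactome.tsv`, `complexes.tsv`, `truth_pairs.tsv` and
#' `truth_subcomplexes.tsv` under `dir`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # OBO
  e <- world$dag$edges
  stanzas <- vapply(world$dag$terms, function(t) {
    rel <- e[e$child == t, , drop = FALSE]
    lines <- c("[Term]", paste("id:", t))
    if (nrow(rel)) {
      is_a <- rel$parent[rel$relation == "is_a"]
      po <- rel$parent[rel$relation == "part_of"]
      lines <- c(lines, paste("is_a:", is_a),
                 if (length(po)) paste("relationship: part_of", po))
    }
    paste(c(lines, ""), collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", stanzas),
             file.path(dir, "ontology.obo"))
  ann_tsv <- function(ann, path) {
    df <- data.frame(
      gene = rep(names(ann$annotations), lengths(ann$annotations)),
      term = unlist(ann$annotations, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  ann_tsv(world$target, file.path(dir, "target.tsv"))
  ann_tsv(world$homolog, file.path(dir, "homolog.tsv"))
  write_network(world$interactome, file.path(dir, "interactome.tsv"))
  write_complexes(world$complexes, file.path(dir, "complexes.tsv"))
  truth <- truth_tables(world)
  write_pairs(truth$pairs, file.path(dir, "truth_pairs.tsv"))
  df <- data.frame(
    subcomplex = rep(names(truth$subcomplexes), lengths(truth$subcomplexes)),
    gene = unlist(truth$subcomplexes, use.names = FALSE))
  utils::write.table(df, file.path(dir, "truth_subcomplexes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
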