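#' Construct a gene-interaction network
#'
#' Undirected graph over gene symbols: edges are unordered, self-loops
#' and duplicates are removed, and isolated (degree-0) nodes are
#' permitted. Evidence scores, when present, gate edge inclusion only —
#' distances treat every retained edge as a binary experimental
#' interaction.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optional
#'   `score` in \[0, 1\].
#' @param nodes optional character vector of additional (isolated) gene
#'   symbols.
#' @return object of class `gene_network`: `nodes` (sorted) and `edges`
#'   (canonicalized data.frame).
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        score = numeric(0))
  } else {
    a <- toupper(as.character(edges[[1]]))
    b <- toupper(as.character(edges[[2]]))
    score <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else
      rep(NA_real_, length(a))
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- lo != hi  # drop self-loops
    edges <- data.frame(gene_a = lo[keep], gene_b = hi[keep],
                        score = score[keep], stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]), , drop = FALSE]
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b,
                         toupper(as.character(nodes)))))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes / edges
#' @param net a [gene_network()].
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[c("gene_a", "gene_b")],
                                directed = FALSE, vertices = net$nodes)
}

#' Load a STRING-style edge list
#'
#' TSV with columns `gene_a`, `gene_b` and an optional `combined_score`;
#' a header row is auto-detected and comment lines starting with `#` are
#' skipped. Rows whose score falls below `score_threshold` are dropped;
#' duplicates and self-loops are collapsed/removed. With
#' `keep_isolated = TRUE` (default) genes that appear only in dropped
#' rows remain in the node set as isolated nodes.
#'
#' @param path TSV file.
#' @param score_threshold minimum evidence score for edge inclusion
#'   (rows without a score always pass).
#' @param keep_isolated keep endpoints of dropped rows as isolated nodes.
#' @return a [gene_network()].
#' @export
load_edge_list <- function(path, score_threshold = 0, keep_isolated = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t")
  # tolerate space-separated files
  if (max(lengths(parts)) == 1L) parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed edge-list row at line ", lineno[bad[1]], " of ", path,
         ": needs at least 2 columns")
  }
  first <- parts[[1]]
  has_header <- grepl("gene", first[1], ignore.case = TRUE) ||
    (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
  if (has_header) { parts <- parts[-1]; lineno <- lineno[-1] }
  if (!length(parts)) stop("edge list has a header but no data rows: ", path)
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 3) p[3] else NA_character_, "")))
  pass <- is.na(sc) | sc >= score_threshold
  iso <- if (keep_isolated) toupper(c(a, b)) else NULL
  gene_network(data.frame(gene_a = a[pass], gene_b = b[pass],
                          score = sc[pass]),
               nodes = iso)
}

#' Write a network as an edge-list TSV
#' @param net a [gene_network()].
#' @param path output path.
#' @param isolated_as_comment record isolated nodes as `# node:` comments
#'   so the file round-trips.
#' @export
write_edge_list <- function(net, path, isolated_as_comment = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tcombined_score", con)
  if (nrow(net$edges)) {
    sc <- ifelse(is.na(net$edges$score), "", format(net$edges$score))
    writeLines(paste(net$edges$gene_a, net$edges$gene_b, sc, sep = "\t"), con)
  }
  if (isolated_as_comment) {
    deg <- degree_counts(net)
    iso <- net$nodes[deg[net$nodes] == 0]
    if (length(iso)) writeLines(paste0("# node: ", iso), con)
  }
  invisible(path)
}

degree_counts <- function(net) {
  deg <- setNames(rep(0L, n_nodes(net)), net$nodes)
  tab <- table(c(net$edges$gene_a, net$edges$gene_b))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Breadth-first shortest-path lengths from one gene
#'
#' Unweighted distances to every gene in the source's connected
#' component; unreachable genes are absent from the result.
#'
#' @param net a [gene_network()].
#' @param source gene symbol.
#' @return named integer vector of distances (includes `source` at 0).
#' @export
shortest_path_lengths <- function(net, source) {
  source <- toupper(source)
  if (!source %in% net$nodes) stop("unknown gene: ", source)
  g <- as_igraph(net)
  d <- igraph::distances(g, v = source)[1, ]
  d <- d[is.finite(d)]
  out <- setNames(as.integer(d), names(d))
  out[order(names(out))]
}

#' Shortest-path centralities per gene
#'
#' Computed within each connected component: eccentricity is the maximum
#' distance to any component member, closeness the reciprocal of the
#' mean distance to the other members (equivalently `(n-1)/sum(d)`), and
#' radiality `(diam + 1 - mean distance)/diam` with `diam` the component
#' diameter. Isolated nodes (and singleton components) get NA metrics
#' rather than zeros. For every non-isolated node the identity
#' `radiality = (diam + 1 - 1/closeness)/diam` holds exactly.
#'
#' @param net a nonempty [gene_network()].
#' @return data.frame: gene, degree, eccentricity, closeness, radiality,
#'   component_id, component_size; sorted by gene.
#' @export
centralities <- function(net) {
  if (n_nodes(net) == 0) stop("empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  deg <- degree_counts(net)
  # deterministic component ids: by decreasing size then lexicographic
  # smallest member
  members <- split(names(comp$membership), comp$membership)
  firsts <- vapply(members, function(m) sort(m)[1], "")
  ord <- order(-comp$csize, firsts)
  newid <- integer(length(ord)); newid[ord] <- seq_along(ord)
  rows <- lapply(seq_along(members), function(ci) {
    genes <- sort(members[[ci]])
    n <- length(genes)
    if (n == 1L) {
      return(data.frame(gene = genes, degree = as.integer(deg[genes]),
                        eccentricity = NA_integer_, closeness = NA_real_,
                        radiality = NA_real_, component_id = newid[ci],
                        component_size = 1L))
    }
    dmat <- igraph::distances(g, v = genes, to = genes)
    diam <- max(dmat)
    meand <- rowSums(dmat) / (n - 1)
    data.frame(gene = genes, degree = as.integer(deg[genes]),
               eccentricity = as.integer(apply(dmat, 1, max)),
               closeness = 1 / meand,
               radiality = (diam + 1 - meand) / diam,
               component_id = newid[ci], component_size = n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a protein-level amino-acid change string
#'
#' Accepts `K700E` (missense), `G83=` (synonymous) and `*`/`X` stop
#' codes, with an optional `p.` prefix. Returns NA fields for strings
#' that do not parse (e.g. `?`).
#'
#' @param x character vector of aa-change strings.
#' @return data.frame: ref, pos, alt.
#' @export
parse_aa_change <- function(x) {
  x <- sub("^p\\.", "", as.character(x))
  m <- regmatches(x, regexec("^([A-Za-z*])([0-9]+)([A-Za-z*=])$", x))
  ref <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")
  alt <- vapply(m, function(g) if (length(g)) g[4] else NA_character_, "")
  data.frame(ref = ref, pos = suppressWarnings(as.integer(pos)), alt = alt,
             stringsAsFactors = FALSE)
}

normalize_mutation_type <- function(x) {
  y <- gsub("[^a-z]", "", tolower(as.character(x)))
  out <- rep("other", length(y))
  out[grepl("missense", y)] <- "substitution_missense"
  out[grepl("codingsilent|synonymous", y)] <- "substitution_synonymous"
  out
}

normalize_fathmm_class <- function(x) {
  y <- tolower(trimws(as.character(x)))
  out <- rep("unspecified", length(y))
  out[grepl("^pathogenic$|^cancer$", y)] <- "pathogenic"
  out[grepl("^neutral$|^passenger", y)] <- "neutral"
  out
}

#' Build a somatic-mutation record table
#'
#' Standardizes a COSMIC-export-style table: mutation types map onto
#' `substitution_missense` / `substitution_synonymous` / `other`, FATHMM
#' predictions onto `pathogenic` / `neutral` / `unspecified`, aa-change
#' strings lose any `p.` prefix, and invariants are enforced (scores in
#' \[0, 1\]; missense changes must parse with ref != alt and position
#' >= 1).
#'
#' @param gene,sample_id,mutation_type,aa_change,histology character
#'   vectors.
#' @param fathmm_prediction FATHMM class labels.
#' @param fathmm_score numeric scores in \[0, 1\] (NA allowed).
#' @return data.frame of class `mutation_records`.
#' @export
mutation_records <- function(gene, sample_id, mutation_type, aa_change,
                             histology, fathmm_prediction, fathmm_score) {
  rec <- data.frame(
    gene = toupper(as.character(gene)),
    sample_id = as.character(sample_id),
    mutation_type = normalize_mutation_type(mutation_type),
    aa_change = sub("^p\\.", "", as.character(aa_change)),
    histology = as.character(histology),
    fathmm_class = normalize_fathmm_class(fathmm_prediction),
    fathmm_score = as.numeric(fathmm_score),
    stringsAsFactors = FALSE
  )
  bad_score <- !is.na(rec$fathmm_score) &
    (rec$fathmm_score < 0 | rec$fathmm_score > 1)
  if (any(bad_score)) {
    stop("FATHMM score outside [0,1] at record ", which(bad_score)[1])
  }
  mis <- rec$mutation_type == "substitution_missense"
  p <- parse_aa_change(rec$aa_change[mis])
  bad <- is.na(p$pos) | p$pos < 1 | p$ref == p$alt | p$alt == "="
  if (any(bad)) {
    stop("missense record with unparseable aa change: '",
         rec$aa_change[mis][bad][1], "'")
  }
  class(rec) <- c("mutation_records", "data.frame")
  rec
}

#' Read a COSMIC-style somatic-mutation table
#'
#' CSV or TSV (by extension) with named columns `gene`, `sample_id`,
#' `mutation_type`, `aa_change`, `histology`, `fathmm_prediction`,
#' `fathmm_score`.
#'
#' @param path file path.
#' @return a [mutation_records()] table.
#' @export
read_mutation_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "#")
  need <- c("gene", "sample_id", "mutation_type", "aa_change", "histology",
            "fathmm_prediction", "fathmm_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  }
  mutation_records(df$gene, df$sample_id, df$mutation_type, df$aa_change,
                   df$histology, df$fathmm_prediction, df$fathmm_score)
}

#' Filter mutations by the study's pathogenicity criteria
#'
#' Keeps records that match the histology AND are missense substitutions
#' AND carry a `pathogenic` FATHMM class AND have a score strictly
#' greater than the threshold (default 0.9, a deliberately stringent
#' raise over FATHMM's nominal 0.5 to suppress false positives).
#' Records with a missing score are dropped. Idempotent.
#'
#' @param records a [mutation_records()] table.
#' @param histology histology label to keep (exact match).
#' @param score_threshold FATHMM score threshold in \[0, 1\].
#' @return the surviving records.
#' @export
filter_mutations <- function(records, histology, score_threshold = 0.9) {
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  keep <- records$histology == histology &
    records$mutation_type == "substitution_missense" &
    records$fathmm_class == "pathogenic" &
    !is.na(records$fathmm_score) &
    records$fathmm_score > score_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by filtered-mutation burden on the network
#'
#' Superimposes already-filtered mutation records on the gene network:
#' per gene, the surviving-record count, the most frequent aa change
#' with its sample count (ties broken lexicographically), and the gene's
#' centrality record. Genes absent from the network are still reported,
#' flagged `off_network`. Rows are sorted by descending count, ties
#' lexicographic by gene — the output is deterministic and invariant to
#' record and edge order.
#'
#' @param net a [gene_network()].
#' @param records filtered [mutation_records()].
#' @return data.frame of class `prioritization`.
#' @export
prioritize <- function(net, records) {
  cent <- if (n_nodes(net) > 0) centralities(net) else NULL
  if (nrow(records) == 0) {
    out <- data.frame(gene = character(0), n_mutations = integer(0),
                      top_aa_change = character(0), top_change_n = integer(0),
                      off_network = logical(0), degree = integer(0),
                      eccentricity = integer(0), closeness = numeric(0),
                      radiality = numeric(0))
    class(out) <- c("prioritization", "data.frame")
    return(out)
  }
  genes <- sort(unique(records$gene))
  rows <- lapply(genes, function(g) {
    rg <- records[records$gene == g, , drop = FALSE]
    tab <- table(rg$aa_change)
    tab <- tab[order(-as.integer(tab), names(tab))]
    data.frame(gene = g, n_mutations = nrow(rg),
               top_aa_change = names(tab)[1],
               top_change_n = as.integer(tab[1]),
               off_network = !(g %in% net$nodes))
  })
  out <- do.call(rbind, rows)
  if (!is.null(cent)) {
    out <- merge(out, cent[c("gene", "degree", "eccentricity", "closeness",
                             "radiality")], by = "gene", all.x = TRUE)
  } else {
    out$degree <- NA_integer_; out$eccentricity <- NA_integer_
    out$closeness <- NA_real_; out$radiality <- NA_real_
  }
  out <- out[order(-out$n_mutations, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prioritization", "data.frame")
  out
}

#' Write the centrality table / prioritization report as TSV
#'
#' Fixed column order; numeric columns at full precision.
#' @param x a [centralities()] or [prioritize()] result.
#' @param path output path.
#' @export
write_report_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
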