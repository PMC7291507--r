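# Interolog transfer of a template bait->prey PPI network onto the query
# species, condition-overlay node decoration and export.

#' Read a template bait->prey edge list
#'
#' TSV with columns `bait`, `prey` and optionally `evidence`.
#'
#' @param path Path to the TSV file.
#' @return Data frame `bait`, `prey`, `evidence`; self-edges are kept but
#'   flagged in a logical `self` column.
#' @export
read_template_edges <- function(path) {
  df <- read_tsv(path)
  if (!all(c("bait", "prey") %in% names(df)))
    stop_("template edge TSV needs columns: bait, prey")
  if (is.null(df$evidence)) df$evidence <- NA_character_
  df$self <- df$bait == df$prey
  df
}

#' Transfer a template network through ortholog groups
#'
#' For every template edge (b, p), emits every query-species pair (B, P)
#' where B is a query ortholog of b and P of p (the full product for
#' many-to-many groups), keeping directionality (bait -> prey) and
#' provenance. Template edges with an unmapped endpoint produce no edge
#' and are recorded in the skip log.
#'
#' @param template_edges Data frame `bait`, `prey` (optionally
#'   `evidence`), template-species accessions.
#' @param orthologs Mapping between species: either a data frame with
#'   columns `template` and `query` (optionally `group_id`), or an RBH
#'   table from [reciprocal_best_hits()] (columns `query_a` = query
#'   species, `subject_b` = template species).
#' @return Object of class `"ppi_network"`: list with `edges` (data frame
#'   `source`, `target`, `template_bait`, `template_prey`, `bait_group`,
#'   `prey_group`, `evidence`), `nodes` (all query accessions appearing in
#'   the map, so unmapped-but-known proteins can still be drawn), and
#'   `skipped` (template edges without a full mapping, with reasons).
#' @export
transfer_network <- function(template_edges, orthologs) {
  if (all(c("query_a", "subject_b") %in% names(orthologs)))
    orthologs <- data.frame(template = orthologs$subject_b,
                            query = orthologs$query_a,
                            group_id = paste0("rbh:", orthologs$subject_b),
                            stringsAsFactors = FALSE)
  if (!all(c("template", "query") %in% names(orthologs)))
    stop_("'orthologs' needs columns template and query")
  if (is.null(orthologs$group_id))
    orthologs$group_id <- paste0("map:", orthologs$template)
  if (is.null(template_edges$evidence))
    template_edges$evidence <- NA_character_
  qmap <- split(seq_len(nrow(orthologs)), orthologs$template)
  edges <- list(); skipped <- list()
  for (k in seq_len(nrow(template_edges))) {
    b <- template_edges$bait[k]; p <- template_edges$prey[k]
    bi <- qmap[[b]]; pi <- qmap[[p]]
    if (is.null(bi) || is.null(pi)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        bait = b, prey = p,
        reason = paste0("unmapped ",
                        paste(c("bait"[is.null(bi)], "prey"[is.null(pi)]),
                              collapse = " and ")),
        stringsAsFactors = FALSE)
      next
    }
    grid <- expand.grid(bi = bi, pi = pi)
    edges[[length(edges) + 1L]] <- data.frame(
      source = orthologs$query[grid$bi], target = orthologs$query[grid$pi],
      template_bait = b, template_prey = p,
      bait_group = orthologs$group_id[grid$bi],
      prey_group = orthologs$group_id[grid$pi],
      evidence = template_edges$evidence[k], stringsAsFactors = FALSE)
  }
  edf <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(), target = character(),
               template_bait = character(), template_prey = character(),
               bait_group = character(), prey_group = character(),
               evidence = character())
  edf <- sort_df(edf, c("source", "target", "template_bait", "template_prey"))
  rownames(edf) <- NULL
  sdf <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(bait = character(), prey = character(), reason = character())
  structure(list(edges = edf,
                 nodes = sort(unique(c(edf$source, edf$target,
                                       orthologs$query))),
                 skipped = sdf),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("Interolog PPI network: %d node(s), %d edge(s), %d template edge(s) skipped\n",
              length(x$nodes), nrow(x$edges), nrow(x$skipped)))
  invisible(x)
}

#' Decorate network nodes with condition-overlay states
#'
#' Encodes, per node, the legend of the condition-overlay figure: shape
#' `CIRCLE` for bi-level regulated proteins (six condition sectors),
#' `RECTANGLE` for proteins that are only differentially expressed, and
#' `DIAMOND` for everything else. Sector triples are ordered left to
#' right HIGH, OPT, LOW; the upper triple is quantitative-proteome
#' detection, the lower phosphoproteome detection. Circle borders are
#' `CYAN` when the protein is significantly regulated at >= 1.5-fold
#' (a reported bi-level record), `PINK` below that; rectangles have
#' `GREY` and diamonds `BLACK` borders.
#'
#' @param network A `"ppi_network"` (or character vector of accessions).
#' @param expression Combined `"expression_results"` for both contrasts
#'   (rows with call `UP`/`DOWN` mark a protein as differentially
#'   expressed).
#' @param bilevel `"bilevel_records"` from [identify_bilevel()]; the
#'   candidate set defines circles, the reported flag the cyan border.
#' @param quant_presence Data frame from [presence_by_condition()].
#' @param phospho_presence Data frame `accession`, `LOW`, `OPT`, `HIGH`
#'   (e.g. from [phospho_presence()]).
#' @return Data frame of class `"node_decorations"`: `accession`, `shape`,
#'   `quant_high`, `quant_opt`, `quant_low`, `phospho_high`,
#'   `phospho_opt`, `phospho_low`, `border`.
#' @export
decorate_nodes <- function(network, expression, bilevel,
                           quant_presence = NULL, phospho_presence = NULL) {
  nodes <- if (inherits(network, "ppi_network")) network$nodes
           else sort(unique(as.character(network)))
  de_acc <- unique(expression$accession[expression$call %in% c("UP", "DOWN")])
  bi_acc <- bilevel$accession[bilevel$candidate]
  rep_acc <- bilevel$accession[bilevel$reported]
  look <- function(tab, acc, col) {
    if (is.null(tab)) return(rep(FALSE, length(acc)))
    v <- tab[[col]][match(acc, tab$accession)]
    !is.na(v) & v
  }
  shape <- ifelse(nodes %in% bi_acc, "CIRCLE",
                  ifelse(nodes %in% de_acc, "RECTANGLE", "DIAMOND"))
  border <- ifelse(shape == "CIRCLE",
                   ifelse(nodes %in% rep_acc, "CYAN", "PINK"),
                   ifelse(shape == "RECTANGLE", "GREY", "BLACK"))
  out <- data.frame(
    accession = nodes, shape = shape,
    quant_high = look(quant_presence, nodes, "HIGH"),
    quant_opt = look(quant_presence, nodes, "OPT"),
    quant_low = look(quant_presence, nodes, "LOW"),
    phospho_high = look(phospho_presence, nodes, "HIGH"),
    phospho_opt = look(phospho_presence, nodes, "OPT"),
    phospho_low = look(phospho_presence, nodes, "LOW"),
    border = border, stringsAsFactors = FALSE)
  class(out) <- c("node_decorations", "data.frame")
  out
}

#' Per-condition phosphodetection presence
#'
#' @param inventories Named list of [aggregate_sites()] inventories.
#' @return Data frame `accession`, `LOW`, `OPT`, `HIGH` (logical).
#' @export
phospho_presence <- function(inventories) {
  rows <- lapply(inventories, function(inv)
    data.frame(accession = inv$accession, LOW = any(inv$sites$LOW),
               OPT = any(inv$sites$OPT), HIGH = any(inv$sites$HIGH),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify edges by endpoint shapes
#'
#' `GREEN` between two bi-level (circle) nodes, `PURPLE` between a circle
#' and a differentially-expressed (rectangle) node, `OTHER` otherwise;
#' symmetric in endpoint order.
#'
#' @param network A `"ppi_network"` or its `edges` data frame.
#' @param decorations [decorate_nodes()] output covering all endpoints.
#' @return The edge data frame with an added `class` column.
#' @export
classify_edges <- function(network, decorations) {
  edges <- if (inherits(network, "ppi_network")) network$edges else network
  sh <- stats::setNames(decorations$shape, decorations$accession)
  s1 <- sh[edges$source]; s2 <- sh[edges$target]
  if (anyNA(s1) || anyNA(s2)) {
    missing <- unique(c(edges$source[is.na(s1)], edges$target[is.na(s2)]))
    stop_("missing decoration for node(s): ", paste(missing, collapse = ", "))
  }
  pair <- paste(pmin(s1, s2), pmax(s1, s2))
  edges$class <- ifelse(pair == "CIRCLE CIRCLE", "GREEN",
                        ifelse(pair == "CIRCLE RECTANGLE", "PURPLE", "OTHER"))
  edges
}

#' Extract a radius-limited subnetwork
#'
#' Breadth-first neighbourhood of a seed accession, ignoring edge
#' direction, up to `radius` hops; the induced edges are included.
#'
#' @param network A `"ppi_network"`.
#' @param seed Seed accession (must be a node).
#' @param radius Number of hops (0 = the seed alone).
#' @return A `"ppi_network"` restricted to the neighbourhood.
#' @export
extract_subnetwork <- function(network, seed, radius = 1) {
  stopifnot(inherits(network, "ppi_network"))
  if (!seed %in% network$nodes) {
    near <- utils::head(agrep(seed, network$nodes, value = TRUE,
                              max.distance = 0.3), 5L)
    stop_("seed '", seed, "' not in network",
          if (length(near)) paste0("; nearest matches: ",
                                   paste(near, collapse = ", ")) else "")
  }
  g <- igraph::graph_from_data_frame(
    network$edges[c("source", "target")], directed = FALSE,
    vertices = network$nodes)
  keep <- names(igraph::ego(g, order = radius, nodes = seed)[[1L]])
  edges <- network$edges[network$edges$source %in% keep &
                           network$edges$target %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = sort(keep),
                 skipped = network$skipped[0, , drop = FALSE]),
            class = "ppi_network")
}

#' Read a pathway annotation TSV
#'
#' Columns `accession`, `pathway` (one row per membership).
#'
#' @param path Path to the TSV file.
#' @return Data frame `accession`, `pathway`.
#' @export
read_pathway_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("accession", "pathway") %in% names(df)))
    stop_("pathway TSV needs columns: accession, pathway")
  if (any(!nzchar(df$pathway))) stop_("pathway names must be non-empty")
  df
}

#' Summarise pathways by regulation class
#'
#' For each of the four cross-condition regulation classes, the sorted set
#' of pathways hit by at least one member protein. Unannotated proteins
#' are counted separately.
#'
#' @param classes Data frame `accession`, `class` (from
#'   [classify_regulation_table()]).
#' @param annotation Data frame `accession`, `pathway`.
#' @return Data frame `class`, `pathway`, with attribute `"unannotated"`
#'   (named integer vector of unannotated members per class).
#' @export
summarize_pathways <- function(classes, annotation) {
  if (!nrow(annotation)) stop_("annotation must cover at least one protein")
  cross <- c("UP_UP", "DOWN_DOWN", "UP22_DOWN40", "DOWN22_UP40")
  rows <- list(); unann <- stats::setNames(integer(length(cross)), cross)
  for (cl in cross) {
    members <- classes$accession[classes$class == cl]
    ann <- annotation[annotation$accession %in% members, , drop = FALSE]
    unann[cl] <- sum(!members %in% annotation$accession)
    pw <- sort(unique(ann$pathway))
    if (length(pw))
      rows[[cl]] <- data.frame(class = cl, pathway = pw,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), pathway = character())
  rownames(out) <- NULL
  attr(out, "unannotated") <- unann
  out
}

# ---- export -----------------------------------------------------------

legend_palette <- function() {
  list(quant = c(HIGH = "#f8a0c8", OPT = "#b8e0a0", LOW = "#6699e0"),
       phospho = c(HIGH = "#f0a030", OPT = "#40a040", LOW = "#30c8d0"),
       border = c(CYAN = "#00b0c0", PINK = "#f070a0", GREY = "#909090",
                  BLACK = "#000000"),
       edge = c(GREEN = "#209020", PURPLE = "#8040b0", OTHER = "#b0b0b0"),
       empty = "#ffffff")
}

#' Export a decorated network
#'
#' Writes the network in one of three formats. `SIF` is the plain
#' `source pp target` dialect (isolated nodes as single-column lines).
#' `GraphML` carries all node decorations and the edge class as typed
#' attributes and round-trips through igraph. `SVG` renders the full
#' legend encoding - six-sector circles (upper triple quantitative, lower
#' triple phospho detection, both HIGH/OPT/LOW left to right), striped
#' rectangles, diamonds, border and edge colours - with a deterministic
#' force-directed layout: the same seed yields byte-identical files.
#'
#' @param network A `"ppi_network"`.
#' @param decorations [decorate_nodes()] output.
#' @param edge_classes [classify_edges()] output (edges with a `class`
#'   column); defaults to all-`OTHER`.
#' @param file Output path.
#' @param format `"SVG"`, `"GraphML"` or `"SIF"`.
#' @param seed Layout seed for SVG (default 1).
#' @param include_isolated Draw nodes without edges (default `TRUE`).
#' @return `file`, invisibly.
#' @export
export_network <- function(network, decorations, edge_classes = NULL,
                           file, format = c("SVG", "GraphML", "SIF"),
                           seed = 1L, include_isolated = TRUE) {
  format <- match.arg(format)
  edges <- edge_classes
  if (is.null(edges)) {
    edges <- network$edges
    edges$class <- rep("OTHER", nrow(edges))
  }
  nodes <- if (include_isolated) network$nodes
           else sort(unique(c(edges$source, edges$target)))
  dec <- decorations[match(nodes, decorations$accession), , drop = FALSE]
  if (anyNA(dec$accession))
    stop_("decorations must cover all exported nodes")
  switch(format,
         SIF = export_sif(edges, nodes, file),
         GraphML = export_graphml(edges, dec, nodes, file),
         SVG = export_svg(edges, dec, nodes, file, seed))
  invisible(file)
}

export_sif <- function(edges, nodes, file) {
  lines <- character()
  if (nrow(edges))
    lines <- paste(edges$source, "pp", edges$target, sep = "\t")
  iso <- setdiff(nodes, c(edges$source, edges$target))
  writeLines(c(lines, iso), file)
}

export_graphml <- function(edges, dec, nodes, file) {
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target", "template_bait", "template_prey",
            "evidence", "class")],
    directed = TRUE, vertices = cbind(name = dec$accession,
                                      dec[-1L]))
  igraph::write_graph(g, file, format = "graphml")
}

#' Read back a GraphML network export
#'
#' @param file A GraphML file written by [export_network()].
#' @return List with `edges` and `decorations` data frames.
#' @export
read_graphml_network <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  names(ed)[1:2] <- c("source", "target")
  names(vd)[names(vd) == "name"] <- "accession"
  vd <- vd[names(vd) != "id"]
  for (cc in grep("^(quant|phospho)_", names(vd), value = TRUE))
    vd[[cc]] <- as.logical(vd[[cc]])
  rownames(vd) <- rownames(ed) <- NULL
  list(edges = ed, decorations = vd)
}

fmt_num <- function(x) sprintf("%.2f", x)

svg_sector <- function(cx, cy, r, a0, a1, fill) {
  x0 <- cx + r * cos(a0); y0 <- cy + r * sin(a0)
  x1 <- cx + r * cos(a1); y1 <- cy + r * sin(a1)
  sprintf('<path d="M %s %s L %s %s A %s %s 0 0 1 %s %s Z" fill="%s" stroke="none"/>',
          fmt_num(cx), fmt_num(cy), fmt_num(x0), fmt_num(y0),
          fmt_num(r), fmt_num(r), fmt_num(x1), fmt_num(y1), fill)
}

svg_node <- function(x, y, d, pal) {
  r <- 11
  out <- character()
  if (d$shape == "CIRCLE") {
    # six sectors: upper half quant, lower half phospho; left->right
    # HIGH, OPT, LOW. Upper half spans pi..2pi (SVG y grows downward).
    up <- c(d$quant_high, d$quant_opt, d$quant_low)
    lo <- c(d$phospho_high, d$phospho_opt, d$phospho_low)
    upcol <- ifelse(up, pal$quant, pal$empty)
    locol <- ifelse(lo, pal$phospho, pal$empty)
    ang_up <- seq(pi, 2 * pi, length.out = 4L)
    for (k in 1:3)
      out <- c(out, svg_sector(x, y, r, ang_up[k], ang_up[k + 1L], upcol[k]))
    # lower half 0..pi runs right->left on screen; reverse for H,O,L
    ang_lo <- seq(0, pi, length.out = 4L)
    for (k in 1:3)
      out <- c(out, svg_sector(x, y, r, ang_lo[k], ang_lo[k + 1L],
                               rev(locol)[k]))
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="2"/>',
      fmt_num(x), fmt_num(y), fmt_num(r), pal$border[[d$border]]))
  } else if (d$shape == "RECTANGLE") {
    w <- 24; h <- 14; strip <- 6
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="1.5"/>',
              fmt_num(x - w / 2), fmt_num(y - h / 2), fmt_num(w), fmt_num(h),
              pal$empty, pal$border[[d$border]]),
      if (d$quant_high)
        sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                fmt_num(x - w / 2), fmt_num(y - h / 2), fmt_num(strip),
                fmt_num(h), pal$quant[["HIGH"]]),
      if (d$quant_low)
        sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                fmt_num(x + w / 2 - strip), fmt_num(y - h / 2),
                fmt_num(strip), fmt_num(h), pal$quant[["LOW"]]))
  } else {
    out <- c(out, sprintf(
      '<polygon points="%s,%s %s,%s %s,%s %s,%s" fill="%s" stroke="%s" stroke-width="1.5"/>',
      fmt_num(x), fmt_num(y - r), fmt_num(x + r), fmt_num(y),
      fmt_num(x), fmt_num(y + r), fmt_num(x - r), fmt_num(y),
      pal$empty, pal$border[["BLACK"]]))
  }
  c(out, sprintf('<text x="%s" y="%s" font-size="7" text-anchor="middle">%s</text>',
                 fmt_num(x), fmt_num(y + r + 8), d$accession))
}

export_svg <- function(edges, dec, nodes, file, seed) {
  pal <- legend_palette()
  wd <- 640; ht <- 480; margin <- 40
  if (length(nodes)) {
    g <- igraph::graph_from_data_frame(
      unique(edges[c("source", "target")]), directed = FALSE,
      vertices = nodes)
    set.seed(as.integer(seed))
    xy <- igraph::layout_with_fr(g, niter = 250)
    if (nrow(xy) == 1L) xy <- matrix(c(0, 0), 1L)
    rng <- apply(xy, 2L, range)
    span <- pmax(rng[2L, ] - rng[1L, ], 1e-9)
    xy <- sweep(sweep(xy, 2L, rng[1L, ]), 2L, span, "/")
    xy[, 1L] <- margin + xy[, 1L] * (wd - 2 * margin)
    xy[, 2L] <- margin + xy[, 2L] * (ht - 2 * margin)
    rownames(xy) <- nodes
  } else xy <- matrix(numeric(), 0L, 2L)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
            wd, ht),
    '<rect width="100%" height="100%" fill="#ffffff"/>')
  for (k in seq_len(nrow(edges))) {
    a <- xy[edges$source[k], ]; b <- xy[edges$target[k], ]
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
      fmt_num(a[1]), fmt_num(a[2]), fmt_num(b[1]), fmt_num(b[2]),
      pal$edge[[edges$class[k]]]))
  }
  for (i in seq_along(nodes))
    lines <- c(lines, svg_node(xy[i, 1L], xy[i, 2L],
                               as.list(dec[i, ]), pal))
  lines <- c(lines, "</svg>")
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}
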