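# Interolog transfer, decoration, edge classes, subnetworks, pathways,
# export formats.

map_df <- function(...) {
  m <- list(...)
  data.frame(template = vapply(m, `[[`, "", 1),
             query = vapply(m, `[[`, "", 2),
             group_id = vapply(m, function(x) x[3] %||% paste0("g_", x[1]), ""),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.na(a) || is.null(a)) b else a

test_that("one-to-one orthologs transfer each template edge once", {
  te <- data.frame(bait = "b", prey = "p", evidence = "y2h")
  net <- transfer_network(te, map_df(c("b", "B"), c("p", "P")))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$source, "B")
  expect_equal(net$edges$target, "P")
  expect_equal(net$edges$template_bait, "b")
  expect_equal(nrow(net$skipped), 0L)
})

test_that("unmapped endpoints produce skip-log entries, not edges", {
  te <- data.frame(bait = c("b", "x"), prey = c("p", "p"))
  net <- transfer_network(te, map_df(c("b", "B"), c("p", "P")))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$skipped$bait, "x")
  expect_match(net$skipped$reason, "bait")
})

test_that("many-to-many groups emit the full product with shared provenance", {
  te <- data.frame(bait = "b", prey = "p")
  om <- map_df(c("b", "B1", "gb"), c("b", "B2", "gb"), c("p", "P", "gp"))
  net <- transfer_network(te, om)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$source, c("B1", "B2"))
  expect_equal(unique(net$edges$template_bait), "b")
  expect_equal(unique(net$edges$bait_group), "gb")
  expect_equal(unique(net$edges$prey_group), "gp")
  # oracle: |bait group| x |prey group| combinations
  expect_equal(nrow(net$edges), 2L * 1L)
})

test_that("a perfect 1:1 map transfers every mappable template edge", {
  ds <- generate_dataset(sim_config(seed = 71, n_proteins = 30,
                                    n_template_proteins = 30,
                                    ortholog_fraction = 1,
                                    phospho_fraction = 0,
                                    n_template_edges = 25))
  om <- ds$truth$ortholog_pairs
  net <- transfer_network(ds$template_edges, om)
  expect_equal(nrow(unique(net$edges[c("source", "target")])),
               nrow(unique(ds$template_edges[c("bait", "prey")])))
  # soundness: every inferred edge's provenance exists in the template
  key_t <- paste(ds$template_edges$bait, ds$template_edges$prey)
  expect_true(all(paste(net$edges$template_bait,
                        net$edges$template_prey) %in% key_t))
})

fixture_network <- function() {
  # bait->prey template mimicking the kinase -> glutamate synthase link
  te <- data.frame(bait = c("hikT", "hikT", "otherT"),
                   prey = c("glsT", "regT", "glsT"))
  om <- map_df(c("hikT", "Hik28Q"), c("glsT", "GlsFQ"), c("regT", "RegQ"),
               c("otherT", "OtherQ"))
  transfer_network(te, om)
}

test_that("node decoration follows the legend shape/border/sector rules", {
  net <- fixture_network()
  expression <- rbind(expr_row("GlsFQ", "LOW_vs_OPT", 2.4, 0.001),
                      expr_row("RegQ", "LOW_vs_OPT", 1.8, 0.02),
                      expr_row("Hik28Q", "LOW_vs_OPT", 1.2, 0.30))
  bilevel <- data.frame(accession = c("GlsFQ", "Hik28Q"),
                        candidate = c(TRUE, TRUE),
                        reported = c(TRUE, FALSE))
  qp <- data.frame(accession = c("GlsFQ", "RegQ", "Hik28Q"),
                   LOW = c(TRUE, TRUE, TRUE), OPT = c(TRUE, TRUE, FALSE),
                   HIGH = c(FALSE, TRUE, FALSE))
  pp <- data.frame(accession = c("GlsFQ", "Hik28Q"),
                   LOW = c(TRUE, TRUE), OPT = c(FALSE, FALSE),
                   HIGH = c(FALSE, FALSE))
  dec <- decorate_nodes(net, expression, bilevel, qp, pp)
  d <- function(a) dec[dec$accession == a, ]
  expect_equal(d("GlsFQ")$shape, "CIRCLE")
  expect_equal(d("GlsFQ")$border, "CYAN")     # reported >= 1.5-fold
  expect_equal(d("Hik28Q")$shape, "CIRCLE")
  expect_equal(d("Hik28Q")$border, "PINK")    # candidate below 1.5-fold
  expect_equal(d("RegQ")$shape, "RECTANGLE")
  expect_equal(d("RegQ")$border, "GREY")
  expect_equal(d("OtherQ")$shape, "DIAMOND")
  expect_equal(d("OtherQ")$border, "BLACK")
  # sectors ordered HIGH, OPT, LOW: bi-level protein seen at LOW only
  expect_equal(unlist(d("Hik28Q")[c("quant_high", "quant_opt", "quant_low")],
                      use.names = FALSE), c(FALSE, FALSE, TRUE))
  expect_equal(unlist(d("Hik28Q")[c("phospho_high", "phospho_opt",
                                    "phospho_low")], use.names = FALSE),
               c(FALSE, FALSE, TRUE))
})

test_that("edge classes follow the shape-pair grid, symmetrically", {
  shapes <- c("CIRCLE", "RECTANGLE", "DIAMOND")
  oracle <- function(a, b) {
    if (a == "CIRCLE" && b == "CIRCLE") "GREEN"
    else if (setequal(c(a, b), c("CIRCLE", "RECTANGLE"))) "PURPLE"
    else "OTHER"
  }
  for (a in shapes) for (b in shapes) {
    dec <- data.frame(accession = c("n1", "n2"), shape = c(a, b))
    e <- data.frame(source = "n1", target = "n2")
    expect_equal(classify_edges(e, dec)$class, oracle(a, b),
                 info = paste(a, b))
    e2 <- data.frame(source = "n2", target = "n1")
    expect_equal(classify_edges(e2, dec)$class, oracle(a, b))
  }
  expect_error(classify_edges(data.frame(source = "n1", target = "zz"),
                              data.frame(accession = "n1",
                                         shape = "CIRCLE")),
               "missing decoration")
})

test_that("subnetwork extraction is a breadth-first neighbourhood", {
  net <- fixture_network()
  sub0 <- extract_subnetwork(net, "GlsFQ", 0)
  expect_equal(sub0$nodes, "GlsFQ")
  expect_equal(nrow(sub0$edges), 0L)
  sub1 <- extract_subnetwork(net, "Hik28Q", 1)
  expect_true("GlsFQ" %in% sub1$nodes)   # the direct kinase-GlsF link
  expect_error(extract_subnetwork(net, "GlsF", 1), "nearest|not in")
})

test_that("random-graph neighbourhoods match the brute-force BFS oracle", {
  set.seed(72)
  nodes <- sprintf("N%02d", 1:20)
  p <- t(combn(nodes, 2))
  keep <- runif(nrow(p)) < 0.12
  edges <- data.frame(source = p[keep, 1], target = p[keep, 2],
                      template_bait = "b", template_prey = "p",
                      bait_group = "g", prey_group = "g", evidence = NA)
  net <- structure(list(edges = edges, nodes = nodes,
                        skipped = data.frame()), class = "ppi_network")
  for (seed_node in c("N01", "N07", "N15")) {
    sub <- extract_subnetwork(net, seed_node, 2)
    expect_equal(sub$nodes, bfs_oracle(edges, seed_node, 2))
  }
})

test_that("pathway summaries group by regulation class", {
  classes <- data.frame(accession = c("A", "B", "C", "D"),
                        class = c("UP_UP", "UP_UP", "DOWN_DOWN", "UP22_DOWN40"))
  ann <- data.frame(accession = c("A", "B", "B", "D"),
                    pathway = c("Nitrogen metabolism", "Photosynthesis",
                                "Ribosome", "Photosynthesis"))
  tab <- summarize_pathways(classes, ann)
  expect_setequal(tab$pathway[tab$class == "UP_UP"],
                  c("Nitrogen metabolism", "Photosynthesis", "Ribosome"))
  expect_equal(tab$pathway[tab$class == "UP22_DOWN40"], "Photosynthesis")
  expect_equal(attr(tab, "unannotated")[["DOWN_DOWN"]], 1L)  # C unannotated
  # protein with two pathways appears under both
  expect_equal(sum(tab$class == "UP_UP" &
                     tab$pathway %in% c("Photosynthesis", "Ribosome")), 2L)
  # group-by oracle on a larger random annotation
  set.seed(73)
  cls <- data.frame(accession = sprintf("P%02d", 1:30),
                    class = sample(c("UP_UP", "DOWN_DOWN", "UP22_DOWN40",
                                     "DOWN22_UP40"), 30, TRUE))
  ann2 <- data.frame(accession = sample(cls$accession, 40, TRUE),
                     pathway = sample(c("pw1", "pw2", "pw3"), 40, TRUE))
  got <- summarize_pathways(cls, ann2)
  want <- unique(merge(cls, ann2)[c("class", "pathway")])
  want <- want[order(want$class, want$pathway), ]
  got_key <- paste(got$class, got$pathway)
  expect_setequal(got_key, paste(want$class, want$pathway))
})

decorated_fixture <- function() {
  net <- fixture_network()
  expression <- expr_row("RegQ", "LOW_vs_OPT", 1.8, 0.02)
  bilevel <- data.frame(accession = c("GlsFQ", "Hik28Q"),
                        candidate = TRUE, reported = TRUE)
  dec <- decorate_nodes(net, expression, bilevel,
                        data.frame(accession = "GlsFQ", LOW = TRUE,
                                   OPT = TRUE, HIGH = FALSE),
                        data.frame(accession = "GlsFQ", LOW = TRUE,
                                   OPT = FALSE, HIGH = FALSE))
  list(net = net, dec = dec, ec = classify_edges(net, dec))
}

test_that("SIF export lists edges and isolated nodes", {
  fx <- decorated_fixture()
  path <- withr::local_tempfile(fileext = ".sif")
  export_network(fx$net, fx$dec, fx$ec, path, "SIF")
  lines <- readLines(path)
  expect_true(any(grepl("Hik28Q\tpp\tGlsFQ", lines)))
})

test_that("GraphML round-trips nodes, edges and all decorations", {
  fx <- decorated_fixture()
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(fx$net, fx$dec, fx$ec, path, "GraphML")
  back <- read_graphml_network(path)
  expect_setequal(back$decorations$accession, fx$net$nodes)
  m <- match(fx$dec$accession, back$decorations$accession)
  for (cc in c("shape", "border", "quant_low", "phospho_low"))
    expect_equal(back$decorations[[cc]][m], fx$dec[[cc]],
                 ignore_attr = TRUE)
  expect_equal(nrow(back$edges), nrow(fx$ec))
  expect_setequal(back$edges$class, fx$ec$class)
})

test_that("SVG export is deterministic and renders every node", {
  fx <- decorated_fixture()
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  export_network(fx$net, fx$dec, fx$ec, p1, "SVG", seed = 11)
  export_network(fx$net, fx$dec, fx$ec, p2, "SVG", seed = 11)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  svg <- paste(readLines(p1), collapse = "\n")
  for (acc in fx$net$nodes) expect_match(svg, acc, fixed = TRUE)
  # six-sector circles draw six path sectors per circle node
  expect_equal(lengths(regmatches(svg, gregexpr("<path ", svg))),
               6L * sum(fx$dec$shape == "CIRCLE"))
})

test_that("an empty network still exports valid documents", {
  net <- structure(list(edges = data.frame(source = character(),
                                           target = character(),
                                           template_bait = character(),
                                           template_prey = character(),
                                           bait_group = character(),
                                           prey_group = character(),
                                           evidence = character()),
                        nodes = character(), skipped = data.frame()),
                   class = "ppi_network")
  dec <- decorate_nodes(net, expr_row("x", "LOW_vs_OPT", 1, 1)[0, ],
                        data.frame(accession = character(),
                                   candidate = logical(),
                                   reported = logical()))
  svg <- withr::local_tempfile(fileext = ".svg")
  export_network(net, dec, NULL, svg, "SVG")
  expect_match(paste(readLines(svg), collapse = ""), "</svg>")
  # one-node network renders exactly one shape element
  net1 <- net; net1$nodes <- "Lone"
  dec1 <- decorate_nodes(net1, expr_row("x", "LOW_vs_OPT", 1, 1)[0, ],
                         data.frame(accession = character(),
                                    candidate = logical(),
                                    reported = logical()))
  svg1 <- withr::local_tempfile(fileext = ".svg")
  export_network(net1, dec1, NULL, svg1, "SVG")
  txt <- paste(readLines(svg1), collapse = "\n")
  expect_equal(lengths(regmatches(txt, gregexpr("<polygon ", txt))), 1L)
})
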