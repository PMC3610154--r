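test_that("correlation color scale: endpoints, symmetry, monotonicity", {
  expect_equal(correlation_color(-1), "#FF0000")
  expect_equal(correlation_color(0), "#FFFFFF")
  expect_equal(correlation_color(1), "#0000FF")
  # clamping outside the domain
  expect_equal(correlation_color(-3), "#FF0000")
  expect_equal(correlation_color(2), "#0000FF")
  # odd symmetry: color(-r) is the red/blue mirror of color(r)
  for (r in seq(0, 1, by = 0.1)) {
    pos <- grDevices::col2rgb(correlation_color(r))
    neg <- grDevices::col2rgb(correlation_color(-r))
    expect_equal(unname(pos["red", ]), unname(neg["blue", ]))
    expect_equal(unname(pos["green", ]), unname(neg["green", ]))
  }
  # monotone: blue channel non-decreasing in r
  cols <- grDevices::col2rgb(correlation_color(seq(-1, 1, by = 0.05)))
  expect_true(all(diff(cols["blue", ]) >= 0))
  expect_true(all(diff(cols["red", ]) <= 0))
})

test_that("circle layout places nodes equidistant from the centroid", {
  g <- og_graph()
  for (i in 1:7) g <- og_add_node(g, paste0("n", i))
  g <- layout_network(g, "circle")
  xy <- t(vapply(og_nodes(g), function(n)
    c(og_get_attr(g, "node", n, "graphics.x"),
      og_get_attr(g, "node", n, "graphics.y")), numeric(2)))
  ctr <- colMeans(xy)
  d <- sqrt(rowSums(sweep(xy, 2, ctr)^2))
  expect_lt(max(d) - min(d), 1e-6)
})

test_that("pathway_circles: one circle per pathway, ring of circle centers", {
  g <- og_graph()
  for (i in 1:3) g <- og_add_node(g, paste0("a", i), list(pathway = "P1"))
  for (i in 1:3) g <- og_add_node(g, paste0("b", i), list(pathway = "P2"))
  g <- layout_network(g, "pathway_circles")
  xy <- t(vapply(og_nodes(g), function(n)
    c(og_get_attr(g, "node", n, "graphics.x"),
      og_get_attr(g, "node", n, "graphics.y")), numeric(2)))
  c1 <- colMeans(xy[1:3, ]); c2 <- colMeans(xy[4:6, ])
  expect_gt(sqrt(sum((c1 - c2)^2)), 1)     # distinct circle centers
  d1 <- sqrt(rowSums(sweep(xy[1:3, ], 2, c1)^2))
  expect_lt(max(d1) - min(d1), 1e-6)       # members equidistant from center
  # missing pathway attribute is an error
  g2 <- og_add_node(og_graph(), "x")
  expect_error(layout_network(g2, "pathway_circles"), "pathway")
})

test_that("force-directed layout is deterministic per seed with distinct coords", {
  g <- chain_graph(6)
  g1 <- layout_network(g, "force_directed", seed = 4)
  g2 <- layout_network(g, "force_directed", seed = 4)
  coords <- function(gg) vapply(og_nodes(gg), function(n)
    paste(og_get_attr(gg, "node", n, "graphics.x"),
          og_get_attr(gg, "node", n, "graphics.y")), character(1))
  expect_identical(coords(g1), coords(g2))
  expect_false(identical(coords(g1),
                         coords(layout_network(g, "force_directed", seed = 5))))
  expect_false(anyDuplicated(coords(g1)) > 0)
  expect_true(all(is.finite(vapply(og_nodes(g1), function(n)
    og_get_attr(g1, "node", n, "graphics.x"), numeric(1)))))
})

test_that("tree layout rejects cyclic graphs", {
  g <- og_graph()
  for (id in c("a", "b")) g <- og_add_node(g, id)
  g <- og_add_edge(g, "a", "b"); g <- og_add_edge(g, "b", "a")
  expect_error(layout_network(g, "tree"), "acyclic")
  dag <- chain_graph(3)
  expect_silent(layout_network(dag, "tree"))
})

test_that("SVG rendering: one chart group per mapped node, color endpoints", {
  g <- og_graph()
  e <- small_experiment(3, c("C1", "C2", "C3"), 2)
  for (s in paste0("S", 1:3))
    g <- og_add_node(g, s, list(label = s, sbgn_class = "simple_chemical"))
  g <- map_experiment(g, e, create_missing = FALSE)$graph
  g <- og_add_node(g, "plain", list(label = "plain"))  # unmapped: no chart
  g <- layout_network(g, "circle")
  f <- tempfile(fileext = ".svg")
  render_network(g, f, "svg", charts = chart_spec("bar"))
  svg <- readLines(f)
  expect_equal(sum(grepl("<g class=\"chart\">", svg)), 3)
  expect_equal(sum(grepl("class=\"node\"", svg)), 4)
  unlink(f)
})

test_that("flux edge thickness scales linearly with the attribute", {
  g <- og_graph()
  for (id in c("a", "b", "c")) g <- og_add_node(g, id)
  g <- og_add_edge(g, "a", "b", list(flux = 2))
  g <- og_add_edge(g, "b", "c", list(flux = 4))
  g <- layout_network(g, "circle")
  widths <- function(gg) {
    f <- tempfile(fileext = ".svg")
    render_network(gg, f, "svg", thickness_attr = "flux", t_range = c(0, 8))
    w <- as.numeric(sub(".*stroke-width=\"([0-9.]+)\".*", "\\1",
                        grep("stroke-width", readLines(f), value = TRUE)))
    unlink(f)
    w
  }
  w <- widths(g)
  # t_min = 0: width proportional to |v| -> doubling flux doubles the stroke
  expect_equal(w[2], 2 * w[1])
  expect_equal(w[2], 8)                       # max flux maps to t_max
})

test_that("rendering leaves the graph unchanged and falls back to a layout", {
  g <- chain_graph(3)
  f <- tempfile(fileext = ".svg")
  expect_warning(render_network(g, f, "svg"), "fallback")
  expect_true(file.exists(f))
  # purity: the caller's graph still has no coordinates
  expect_null(og_get_attr(g, "node", "m1", "graphics.x"))
  unlink(f)
})

test_that("HTML export: one area per node, hrefs only where url is set", {
  g <- og_graph()
  for (i in 1:5) g <- og_add_node(g, paste0("n", i), list(label = paste0("N", i)))
  g <- og_set_attr(g, "node", "n1", "url", "https://example.org/a")
  g <- og_set_attr(g, "node", "n4", "url", "https://example.org/b")
  g <- layout_network(g, "grid")
  dir <- tempfile("site")
  out <- export_html(g, dir)
  html <- readLines(out$html)
  areas <- grep("<area ", html, value = TRUE)
  expect_length(areas, 5)
  expect_equal(sum(grepl("href=", areas)), 2)
  expect_true(file.exists(out$image))
  # every node center lies inside its own region
  for (n in og_nodes(g)) {
    b <- omicnet:::node_box(g, n)
    coords <- as.numeric(strsplit(sub(".*coords=\"([^\"]+)\".*", "\\1",
                                      areas[match(n, og_nodes(g))]), ",")[[1]])
    expect_true(b["x"] >= coords[1] && b["x"] <= coords[3])
    expect_true(b["y"] >= coords[2] && b["y"] <= coords[4])
  }
  # empty graph still yields a valid page with zero regions
  out0 <- export_html(og_graph(), tempfile("site0"))
  expect_equal(sum(grepl("<area ", readLines(out0$html))), 0)
  unlink(dir, recursive = TRUE)
})

test_that("PNG rendering writes a non-empty raster when the device exists", {
  skip_if_not(capabilities("png"))
  g <- layout_network(chain_graph(3), "circle")
  f <- tempfile(fileext = ".png")
  render_network(g, f, "png")
  expect_gt(file.info(f)$size, 100)
  unlink(f)
})
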