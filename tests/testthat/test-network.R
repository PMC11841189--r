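mknet <- function(...) {
  rows <- list(...)
  ed <- do.call(rbind, lapply(rows, function(r) {
    data.frame(src = r[[1]], dst = r[[2]], etype = r[[3]],
               rank = as.integer(r[[4]]), directed = as.logical(r[[5]]),
               stringsAsFactors = FALSE)
  }))
  knowledge_network(ed)
}

test_that("filter_by_rank keeps reliable edges and drops isolated nodes", {
  net <- mknet(list("A", "B", "BINDING", 0, FALSE),
               list("B", "C", "PTM", 1, TRUE),
               list("C", "D", "OTHER", 2, TRUE),
               list("D", "E", "BINDING", 3, FALSE))
  expect_equal(nrow(filter_by_rank(net, 2)$edges), 3)
  expect_false("E" %in% filter_by_rank(net, 2)$nodes)
  expect_equal(nrow(filter_by_rank(net, 0)$edges), 1)
  all3 <- mknet(list("A", "B", "BINDING", 3, FALSE))
  expect_warning(empty <- filter_by_rank(all3, 2), "empty")
  expect_equal(nrow(empty$edges), 0)
})

test_that("select_by_terms uses dot-boundary prefix matching", {
  ann <- data.frame(node_id = c("n1", "n2", "n3", "n4"),
                    term = c("30.3", "30.31", "34.21.2", "30.3.1"))
  net <- mknet(list("n1", "n2", "BINDING", 0, FALSE),
               list("n3", "n4", "PTM", 0, TRUE))
  expect_setequal(select_by_terms(net, ann, c("30.3")), c("n1", "n4"))
  expect_setequal(select_by_terms(net, ann, c("34.21")), "n3")
  expect_warning(none <- select_by_terms(net, ann, c("99.9")), "no nodes")
  expect_length(none, 0)
})

test_that("constrained_paths enforces the terminal-TF and length constraints", {
  # direct regulation
  n1 <- mknet(list("S", "T", "TF_REGULATION", 0, TRUE))
  p1 <- constrained_paths(n1, "S", "T")
  expect_length(p1, 1)
  expect_equal(p1[[1]]$nodes, c("S", "T"))
  expect_equal(p1[[1]]$length, 1)

  # two-TF route rejected; binding-then-TF retained
  n2 <- mknet(list("S", "X", "BINDING", 0, FALSE),
              list("X", "T", "TF_REGULATION", 0, TRUE),
              list("S", "Y", "TF_REGULATION", 0, TRUE),
              list("Y", "T", "TF_REGULATION", 0, TRUE))
  p2 <- constrained_paths(n2, "S", "T")
  expect_length(p2, 1)
  expect_equal(p2[[1]]$nodes, c("S", "X", "T"))

  # final edge must be transcriptional
  n3 <- mknet(list("S", "X", "TF_REGULATION", 0, TRUE),
              list("X", "T", "BINDING", 0, FALSE))
  expect_length(constrained_paths(n3, "S", "T"), 0)

  # closest-source reduction
  n4 <- mknet(list("S1", "T", "TF_REGULATION", 0, TRUE),
              list("S2", "X", "BINDING", 0, FALSE),
              list("X", "T", "TF_REGULATION", 0, TRUE))
  p4 <- constrained_paths(n4, c("S1", "S2"), "T")
  expect_length(p4, 1)
  expect_equal(p4[[1]]$nodes, c("S1", "T"))

  # directed interior edges are not traversable backwards
  n5 <- mknet(list("X", "S", "PTM", 0, TRUE),
              list("X", "T", "TF_REGULATION", 0, TRUE))
  expect_length(constrained_paths(n5, "S", "T"), 0)

  # undirected interior edges are traversable both ways
  n6 <- mknet(list("X", "S", "BINDING", 0, FALSE),
              list("X", "T", "TF_REGULATION", 0, TRUE))
  expect_length(constrained_paths(n6, "S", "T"), 1)

  expect_error(constrained_paths(n6, "S", "Z"), "not in network")
})

test_that("constrained_paths equals the exhaustive oracle on random graphs", {
  for (seed in 1:60) {
    case <- random_network_case(seed)
    got <- extraction_signatures(
      constrained_paths(case$net, case$sources, case$target, max_len = 3)
    )
    want <- oracle_paths(case$net, case$sources, case$target, max_len = 3)
    expect_identical(got, want)
  }
})

test_that("every emitted path satisfies the structural invariants", {
  n_checked <- 0
  for (seed in 101:140) {
    case <- random_network_case(seed)
    paths <- constrained_paths(case$net, case$sources, case$target)
    for (p in paths) {
      expect_true(path_is_valid(p, case$net, case$sources, case$target))
      n_checked <- n_checked + 1
    }
    if (length(paths) > 0) {
      lens <- vapply(paths, function(p) p$length, integer(1))
      expect_equal(length(unique(lens)), 1)  # closest-source property
    }
  }
  expect_gt(n_checked, 0)
})

test_that("rank filtering commutes with path extraction", {
  for (seed in 201:230) {
    case <- random_network_case(seed)
    filtered <- tryCatch(filter_by_rank(case$net, 2),
                         warning = function(w) NULL)
    got <- if (is.null(filtered) || !(case$target %in% filtered$nodes)) {
      character(0)
    } else {
      extraction_signatures(
        constrained_paths(filtered, case$sources, case$target)
      )
    }
    want <- oracle_paths(case$net, case$sources, case$target, max_rank = 2)
    expect_identical(got, want)
  }
})

test_that("merge_paths scores hubs and tags roles", {
  # X intermediate on 3 paths to 2 targets
  net <- mknet(list("S1", "X", "BINDING", 0, FALSE),
               list("S2", "X", "PTM", 0, TRUE),
               list("X", "T1", "TF_REGULATION", 0, TRUE),
               list("X", "T2", "TF_REGULATION", 0, TRUE),
               list("S3", "T2", "BINDING", 0, FALSE))
  pbt <- extract_paths(net, c("S1", "S2"), c("T1", "T2"))
  merged <- merge_paths(pbt)
  x <- merged$nodes[merged$nodes$node_id == "X", ]
  expect_equal(x$n_path_occurrences, 4)   # 2 sources x 2 targets
  expect_equal(x$n_distinct_targets, 2)
  expect_equal(merged$hub_ranking$node_id[1], "X")
  expect_equal(x$role, "TF-hub")
  expect_true(all(merged$nodes$role[merged$nodes$node_id %in% c("T1", "T2")] == "target"))
  expect_true(all(merged$nodes$role[merged$nodes$node_id %in% c("S1", "S2")] == "source"))

  # disjoint paths: union network, each intermediate scores (1, 1)
  net2 <- mknet(list("S1", "A", "BINDING", 0, FALSE),
                list("A", "T1", "TF_REGULATION", 0, TRUE),
                list("S2", "B", "PTM", 0, TRUE),
                list("B", "T2", "TF_REGULATION", 0, TRUE))
  m2 <- merge_paths(extract_paths(net2, c("S1", "S2"), c("T1", "T2")))
  expect_equal(nrow(m2$edges), 4)
  ab <- m2$nodes[m2$nodes$node_id %in% c("A", "B"), ]
  expect_equal(ab$n_path_occurrences, c(1, 1))
  expect_equal(ab$n_distinct_targets, c(1, 1))
  expect_equal(ab$role, c("intermediate", "intermediate"))
})

test_that("hub sub-networks contain exactly the paths through the hub", {
  sn <- simulate_network(n_nodes = 60, n_planted = 6, decoy_density = 1,
                         seed = 11, n_hub_targets = 3)
  net <- filter_by_rank(sn$network, 2)
  src <- select_by_terms(net, sn$annotations, c("30.3", "34.21", "34.22"))
  merged <- merge_paths(extract_paths(net, src, sn$truth$targets))
  hub <- sn$truth$hub
  sub <- extract_hub_subnetwork(merged, hub)
  flat <- unlist(sub$paths_by_target, recursive = FALSE)
  expect_true(all(vapply(flat, function(p) hub %in% p$nodes, logical(1))))
  # every edge of the subnetwork lies on a retained path through the hub
  edge_keys <- function(paths) unique(unlist(lapply(paths, function(p) {
    paste(p$edges$src, p$edges$dst, p$edges$etype, p$edges$rank)
  })))
  expect_setequal(paste(sub$edges$src, sub$edges$dst, sub$edges$etype, sub$edges$rank),
                  edge_keys(flat))
  expect_error(extract_hub_subnetwork(merged, "NOPE"), "not in merged")

  # re-merging the union of all hub sub-networks restores the original
  all_paths <- unlist(merged$paths_by_target, recursive = FALSE)
  sig0 <- sort(unname(vapply(all_paths, path_signature, character(1))))
  remerged <- list()
  for (nd in merged$nodes$node_id) {
    sub_nd <- extract_hub_subnetwork(merged, nd)
    for (t in names(sub_nd$paths_by_target)) {
      remerged[[t]] <- union(remerged[[t]] %||% character(0),
                             vapply(sub_nd$paths_by_target[[t]], path_signature,
                                    character(1)))
    }
  }
  expect_equal(sort(unlist(remerged, use.names = FALSE)), sig0)

  # single-path hub: subnetwork is that path
  one <- extract_hub_subnetwork(merged, flat[[1]]$nodes[1])
  flat_one <- unlist(one$paths_by_target, recursive = FALSE)
  expect_true(all(vapply(flat_one, function(p) flat[[1]]$nodes[1] %in% p$nodes,
                         logical(1))))
})

test_that("map_orthologs picks best hits with deterministic tie-breaking", {
  hits <- data.frame(
    query = c("q1", "q1", "q2", "q3", "q3", "q4"),
    subject = c("AT1", "AT2", "AT3", "AT4", "AT5", "AT6"),
    evalue = c(1e-40, 1e-10, 1e-20, 1e-50, 1e-50, 1e-50),
    bitscore = c(300, 100, 200, 290, 310, 500)
  )
  m <- map_orthologs(c("q1", "q2", "q3", "q5"), hits, evalue_cutoff = 1e-30)
  expect_equal(unname(m["q1"]), "AT1")       # best e-value wins
  expect_true(is.na(m["q2"]))                # 1e-20 fails the 1e-30 cutoff
  expect_equal(unname(m["q3"]), "AT5")       # e-value tie -> higher bitscore
  expect_true(is.na(m["q5"]))                # no hits at all
  # bitscore tie -> lexicographically smallest subject
  tie <- data.frame(query = c("q", "q"), subject = c("ATB", "ATA"),
                    evalue = c(1e-50, 1e-50), bitscore = c(300, 300))
  expect_equal(unname(map_orthologs("q", tie)), "ATA")
})

test_that("planted paths are the complete extraction result", {
  for (seed in c(1, 2, 3)) {
    for (dd in c(0, 1.5)) {
      sn <- simulate_network(n_nodes = 70, n_planted = 5, decoy_density = dd,
                             seed = seed, n_hub_targets = 2)
      net <- filter_by_rank(sn$network, 2)
      src <- select_by_terms(net, sn$annotations, c("30.3", "34.21", "34.22"))
      pbt <- extract_paths(net, src, sn$truth$targets)
      got <- sort(unlist(lapply(pbt, function(ps) {
        vapply(ps, function(p) paste(p$nodes, collapse = ">"), character(1))
      }), use.names = FALSE))
      expect_setequal(got, sn$truth$path_nodes)
    }
  }
  # single planted path, no decoys
  sn1 <- simulate_network(n_nodes = 10, n_planted = 1, decoy_density = 0, seed = 4)
  pbt1 <- extract_paths(sn1$network, sn1$truth$sources, sn1$truth$targets)
  expect_equal(sum(lengths(pbt1)), 1)
})
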