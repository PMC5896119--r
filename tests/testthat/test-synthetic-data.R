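test_that("the root gene is a complete ORF with canonical introns", {
  cfg1 <- sim_config(seed = 5, root_exon_count = 1)
  r1 <- generate_root_gene(cfg1)
  expect_equal(nrow(derive_architecture(r1$model)$borders), 0L)

  cfg8 <- sim_config(seed = 1, root_exon_count = 8)
  r8 <- generate_root_gene(cfg8)
  expect_equal(nrow(derive_architecture(r8$model)$borders), 7L)
  expect_true(all(substr(r8$gene$introns, 1, 2) == "GT"))
  expect_true(all(substr(r8$gene$introns, nchar(r8$gene$introns) - 1,
                         nchar(r8$gene$introns)) == "AG"))
  cds <- assemble_cds(r8$model, r8$genome)
  expect_true(cds$complete)
  # border phases are drawn, not forced to zero
  expect_true(any(derive_architecture(r8$model)$borders$phase != 0L))

  r8b <- generate_root_gene(cfg8)
  expect_identical(r8$gene, r8b$gene)
  expect_identical(unclass(r8$genome), unclass(r8b$genome))
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- sim_config(seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(evolve_family(cfg), d1)
  write_simulation(evolve_family(sim_config(seed = 23)), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("zero rates yield identical orthologs and an empty ledger", {
  cfg <- sim_config(seed = 9, species_tree = "((A:1,B:1):1,C:2);",
                    substitution_rate = 0,
                    event_rates = as.list(stats::setNames(
                      rep(0, 7), exonarch:::SIM_EVENT_TYPES)))
  sim <- evolve_family(cfg)
  expect_equal(nrow(sim$ledger), 0L)
  expect_equal(length(sim$models), 3L)
  cds <- lapply(names(sim$models), function(sp) {
    assemble_cds(sim$models[[sp]][[1]], sim$genomes[[sp]])$sequence
  })
  expect_equal(length(unique(unlist(cds))), 1L)
  # with zero rates all borders are shared between any two orthologs
  a1 <- derive_architecture(sim$models$A[[1]])
  a2 <- derive_architecture(sim$models$B[[1]])
  expect_equal(exonarch:::arch_shared_count(a1, a2), nrow(a1$borders))
})

test_that("retrocopies are intron-free and match the ledger", {
  found_any <- FALSE
  for (s in 1:10) {
    cfg <- sim_config(seed = s, substitution_rate = 0,
                      event_rates = list(tandem_duplication = 0,
                                         retrotransposition = 0.15,
                                         intron_gain = 0, intron_loss = 0,
                                         exon_tandem_duplication = 0,
                                         donor_gc_mutation = 0,
                                         gene_loss = 0))
    sim <- evolve_family(cfg)
    retro <- retro_origin_gene_ids(sim$ledger)
    if (length(retro)) found_any <- TRUE
    for (sp in names(sim$models)) {
      for (gid in names(sim$models[[sp]])) {
        base <- sub(paste0(sp, "_"), "", gid)
        n_ex <- length(sim$models[[sp]][[gid]]$transcripts[[1]])
        if (base %in% retro) {
          expect_equal(n_ex, 1L)
        } else {
          expect_gt(n_ex, 1L)
        }
      }
    }
  }
  expect_true(found_any)
})

test_that("gene losses reconcile with the presence/absence matrix", {
  for (s in 1:10) {
    cfg <- sim_config(seed = s, substitution_rate = 0,
                      event_rates = list(tandem_duplication = 0,
                                         retrotransposition = 0,
                                         intron_gain = 0, intron_loss = 0,
                                         exon_tandem_duplication = 0,
                                         donor_gc_mutation = 0,
                                         gene_loss = 0.3))
    sim <- evolve_family(cfg)
    pm <- sim_presence_matrix(sim)
    if (all(pm == 0)) next
    dg <- suppressWarnings(dollo_gainloss(pm, sim$species_tree))
    expect_equal(dg$simfam$n_losses, sim$observable$losses)
  }
})

test_that("intron gains add exactly one border at the recorded phase", {
  for (s in 1:8) {
    cfg <- sim_config(seed = s, substitution_rate = 0,
                      event_rates = list(tandem_duplication = 0,
                                         retrotransposition = 0,
                                         intron_gain = 0.2, intron_loss = 0,
                                         exon_tandem_duplication = 0,
                                         donor_gc_mutation = 0,
                                         gene_loss = 0))
    sim <- evolve_family(cfg)
    led <- sim$ledger[sim$ledger$event == "intron_gain", , drop = FALSE]
    root_borders <- nrow(derive_architecture(
      generate_root_gene(cfg)$model)$borders)
    for (i in seq_len(nrow(led))) {
      off <- as.integer(sub("offset=(\\d+);.*", "\\1", led$detail[i]))
      ph <- as.integer(sub(".*phase=", "", led$detail[i]))
      expect_equal(ph, off %% 3L)
      for (sp in tips_below(sim$species_tree, led$branch[i])) {
        gid <- paste0(sp, "_", led$parent_gene[i])
        m <- sim$models[[sp]][[gid]]
        if (is.null(m)) next
        a <- derive_architecture(m)
        expect_true(any(a$borders$offset == off & a$borders$phase == ph))
      }
    }
    # total border count = root borders + gains along each tip path
    for (sp in names(sim$models)) {
      n_gains_path <- sum(vapply(seq_len(nrow(led)), function(i) {
        sp %in% tips_below(sim$species_tree, led$branch[i])
      }, TRUE))
      a <- derive_architecture(sim$models[[sp]][[1]])
      expect_equal(nrow(a$borders), root_borders + n_gains_path)
    }
  }
})

test_that("every emitted gene is reachable from the root through the ledger", {
  sim <- evolve_family(sim_config(seed = 41, event_rates = list(
    tandem_duplication = 0.2, retrotransposition = 0.1, gene_loss = 0.15)))
  known <- "g1"
  led <- sim$ledger
  creators <- led[led$event %in% c("tandem_duplication",
                                   "retrotransposition"), , drop = FALSE]
  repeat {
    more <- creators$child_gene[creators$parent_gene %in% known &
                                  !(creators$child_gene %in% known)]
    if (!length(more)) break
    known <- c(known, more)
  }
  for (sp in names(sim$models)) {
    for (gid in names(sim$models[[sp]])) {
      expect_true(sub(paste0(sp, "_"), "", gid) %in% known)
    }
  }
  # lost genes are not emitted below their loss branch
  losses <- led[led$event == "gene_loss", , drop = FALSE]
  for (i in seq_len(nrow(losses))) {
    for (sp in tips_below(sim$species_tree, losses$branch[i])) {
      expect_null(sim$models[[sp]][[paste0(sp, "_", losses$parent_gene[i])]])
    }
  }
})
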