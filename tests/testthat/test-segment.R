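test_that("nucleus segmentation recovers the rendered nucleus", {
  cell <- fix_cell("RRE_noRev", seed = 21, channels = "DNA", frames = 10,
                   sample_times_h = seq(0, 8, 0.5), t_end_h = 8)
  nuc <- segment_nucleus(frame_of(cell$movie, 1, "DNA"))
  expect_gte(iou(nuc, cell$movie$ground_truth$nucleus_mask), 0.90)

  cellnl <- fix_cell("RRE_noRev", seed = 21, channels = "DNA", frames = 10,
                     sample_times_h = seq(0, 8, 0.5), t_end_h = 8,
                     optics = fix_optics(noiseless = TRUE))
  nucnl <- segment_nucleus(frame_of(cellnl$movie, 1, "DNA"))
  expect_gte(iou(nucnl, cellnl$movie$ground_truth$nucleus_mask), 0.97)
})

test_that("an empty frame yields a 'no nucleus found' error", {
  expect_error(segment_nucleus(matrix(0, 64, 64)), "no nucleus found")
})

test_that("cell segmentation contains the nucleus and matches ground truth", {
  cell <- fix_cell("RRE_noRev", seed = 22, channels = c("YFP", "DNA"),
                   frames = 10, sample_times_h = seq(0, 8, 0.5), t_end_h = 8)
  nuc <- segment_nucleus(frame_of(cell$movie, 1, "DNA"))
  cm <- segment_cell(frame_of(cell$movie, 1, "YFP"), nuc)
  expect_true(all(cm[nuc]))
  expect_gte(iou(cm, cell$movie$ground_truth$cell_mask), 0.85)
  cm2 <- segment_cell(frame_of(cell$movie, 1, "YFP"), nuc)
  expect_identical(cm, cm2)
})

test_that("background estimation equals the brute-force annulus median", {
  cell <- fix_cell("RRE_noRev", seed = 23, channels = c("YFP", "DNA"),
                   frames = 10, sample_times_h = seq(0, 8, 0.5), t_end_h = 8)
  nuc <- segment_nucleus(frame_of(cell$movie, 1, "DNA"))
  cm <- segment_cell(frame_of(cell$movie, 1, "YFP"), nuc)
  masks <- compartment_masks(nuc, cm)
  img <- frame_of(cell$movie, 1, "YFP")
  bg <- estimate_background(img, masks)
  expect_identical(bg, median(sort(img[masks$background_annulus])))

  # uniform frame: background equals the constant, regardless of the cell
  uni <- matrix(100, nrow(img), ncol(img))
  expect_equal(estimate_background(uni, masks), 100)
  bright <- uni; bright[masks$cell] <- 5000; bright[!masks$cell] <- 90
  expect_equal(estimate_background(bright, masks), 90)
})

test_that("compartment MFI matches hand computation and clamps at zero", {
  nuc <- matrix(FALSE, 40, 40); nuc[15:25, 15:25] <- TRUE
  cm <- matrix(FALSE, 40, 40); cm[5:35, 5:35] <- TRUE
  masks <- compartment_masks(nuc, cm)
  img <- matrix(0, 40, 40); img[nuc] <- 150; img[cm & !nuc] <- 60
  mfi <- compartment_mfi(img, masks, 50)
  expect_equal(mfi$nuclear_mfi, 100)
  expect_equal(mfi$cytoplasmic_mfi, 10)
  mfi0 <- compartment_mfi(img, masks, 1000)
  expect_equal(mfi0$nuclear_mfi, 0)

  # brute-force oracle on a random frame
  set.seed(1)
  rnd <- matrix(runif(1600, 0, 300), 40, 40)
  got <- compartment_mfi(rnd, masks, 20)
  expect_equal(got$nuclear_mfi, mean(pmax(rnd[masks$nucleus] - 20, 0)))
  expect_equal(got$cytoplasmic_mfi, mean(pmax(rnd[masks$cytoplasm] - 20, 0)))
})

test_that("MFI operators are invariant to a constant offset with re-estimated background", {
  cell <- fix_cell("RRE_noRev", seed = 24, channels = c("YFP", "DNA"),
                   frames = 10, sample_times_h = seq(0, 8, 0.5), t_end_h = 8)
  nuc <- segment_nucleus(frame_of(cell$movie, 1, "DNA"))
  cm <- segment_cell(frame_of(cell$movie, 1, "YFP"), nuc)
  masks <- compartment_masks(nuc, cm)
  img <- frame_of(cell$movie, 1, "YFP")
  m1 <- compartment_mfi(img, masks, estimate_background(img, masks))
  img2 <- img + 37
  m2 <- compartment_mfi(img2, masks, estimate_background(img2, masks))
  expect_equal(m1$nuclear_mfi, m2$nuclear_mfi, tolerance = 1e-8)
  expect_equal(m1$cytoplasmic_mfi, m2$cytoplasmic_mfi, tolerance = 1e-8)
})

test_that("punctae detection finds rendered spots and nothing on flat frames", {
  # pick a fixture whose in-core ground-truth punctae are well separated
  # (sub-resolution pairs merge by design; that case is tested below)
  truth <- NULL
  for (s in 25:45) {
    cand <- fix_cell("RRE_noRev", seed = s, channels = c("YFP", "DNA"),
                     frames = 11, sample_times_h = seq(0, 8, 0.5),
                     t_end_h = 8)
    gt <- cand$movie$ground_truth
    sig_px <- cand$optics$psf_sigma / cand$optics$pixel_size
    margin <- 2L * as.integer(ceiling(sig_px)) + 1L
    core <- EBImage::erode(gt$nucleus_mask,
                           EBImage::makeBrush(2L * margin + 1L, "disc"))
    tr <- gt$spots[gt$spots$channel == "YFP", ]
    in_core <- core[cbind(round(tr$y_px) + 1, round(tr$x_px) + 1)]
    # at least three in-core spots, none within the merge scale of any
    # other rendered spot
    dm <- as.matrix(dist(tr[, c("x_px", "y_px")]))
    diag(dm) <- Inf
    if (sum(in_core) >= 3 && all(apply(dm[in_core, , drop = FALSE],
                                       1, min) > 5)) {
      cell <- cand; truth <- tr[in_core, ]
      break
    }
  }
  expect_false(is.null(truth))
  img <- frame_of(cell$movie, 1, "YFP")
  sig_px <- cell$optics$psf_sigma / cell$optics$pixel_size
  sp <- detect_punctae(img, cell$movie$ground_truth$nucleus_mask, sig_px)
  expect_equal(nrow(sp), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((sp$x_px - truth$x_px[i])^2 + (sp$y_px - truth$y_px[i])^2)
    expect_lt(min(d), 1)
  }

  set.seed(2)
  flat <- matrix(rpois(256^2, 100), 256, 256)
  mask <- matrix(FALSE, 256, 256); mask[60:200, 60:200] <- TRUE
  expect_equal(nrow(detect_punctae(flat, mask, sig_px)), 0)
})

test_that("two spots a pixel apart merge into one detection", {
  set.seed(3)
  img <- matrix(rpois(128^2, 100), 128, 128)
  sig_px <- 0.4 / 0.325
  img <- retroflux:::add_spots(img, c(60, 61), c(60, 60), c(800, 800), sig_px)
  mask <- matrix(TRUE, 128, 128)
  sp <- detect_punctae(img, mask, sig_px)
  expect_equal(nrow(sp), 1)
})

test_that("enrichment is one for a flat disk and invariant to intensity scaling", {
  img <- matrix(200, 120, 120)
  nuc <- matrix(FALSE, 120, 120); nuc[30:90, 30:90] <- TRUE
  sp <- data.frame(x_px = 59, y_px = 59, mfi = 200, response = 1)
  en <- punctae_enrichment(sp, img, nuc, 0, 1.23)
  expect_equal(en$mean, 1.0)

  # spot-region MFI 280 over nucleoplasm 100 is by definition 2.8-fold
  img2 <- img; img2[] <- 150
  offs <- retroflux:::disk_offsets(2 * 1.23)
  img2[retroflux:::clip_idx(cbind(offs[, 1] + 60, offs[, 2] + 60), 120, 120)] <- 330
  en2 <- punctae_enrichment(sp, img2, nuc, 50, 1.23)
  expect_equal(en2$mean, 2.8, tolerance = 1e-9)
  en3 <- punctae_enrichment(sp, img2 * 3, nuc, 150, 1.23)
  expect_equal(en3$mean, 2.8, tolerance = 1e-9)  # scale invariance

  expect_equal(punctae_enrichment(NULL, img, nuc, 0, 1.23)$n, 0L)
})
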