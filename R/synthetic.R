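#' Configuration of a synthetic paddy scene
#'
#' Emulates a UAV nadir view of a rice paddy: quasi-grid-arranged green
#' plants (anti-aliased lobed ellipses) on a soil or flooded background,
#' with a configurable fraction of anomalous (chlorotic, undersized,
#' ragged-boundary) plants. Stage presets are monotone early -> mid ->
#' mature in plant radius and overlap probability, mirroring sparse small
#' seedlings growing into a dense canopy; the early stage defaults to a
#' flooded background (paddies are typically flooded at transplanting).
#'
#' @param imageSize `(H, W)` in px.
#' @param stage `"early"`, `"mid"` or `"mature"`.
#' @param nPlants number of plants (default 64, an 8 x 8 planting
#'   grid — a typical seedling density for a patch this size).
#' @param gridJitter sd of the planting-grid jitter in px.
#' @param plantRadius mean plant radius in px (stage preset when `NULL`:
#'   5, 8, 11).
#' @param radiusSd sd of the per-plant radius (preset 0.8, 1.2, 1.6).
#' @param overlapProb probability that a plant is pulled toward a
#'   neighbour to create touching/overlapping canopies (preset 0, 0.15,
#'   0.4).
#' @param background `"soil"` or `"flooded"` (preset: flooded at early,
#'   soil later).
#' @param anomalyFraction fraction of plants drawn anomalous
#'   (default 0.05).
#' @param anomalySpec list: `hueShift` (channel shift toward
#'   yellow/brown, unit scale; default `c(0.20, -0.16, -0.05)` — severe
#'   browning, sized so the displacement measured on extracted features
#'   clears every healthy extreme even after boundary pixels blend with
#'   the background), `sizeFactor` (area factor < 1, default 0.5),
#'   `boundaryRoughness` (default 0.25).
#' @param noiseSd Gaussian channel noise added last (default 0.01).
#' @param seed integer; all randomness derives from it through fixed
#'   sub-streams (placement, identity, appearance, noise), so sibling
#'   stages of a series share placement and anomaly identity.
#' @return a validated config list of class `SceneConfig`.
#' @export
sceneConfig <- function(imageSize = c(160L, 160L),
                        stage = c("early", "mid", "mature"),
                        nPlants = 64L, gridJitter = 1.5,
                        plantRadius = NULL, radiusSd = NULL,
                        overlapProb = NULL, background = NULL,
                        anomalyFraction = 0.05,
                        anomalySpec = list(hueShift = c(0.20, -0.16, -0.05),
                                           sizeFactor = 0.5,
                                           boundaryRoughness = 0.25),
                        noiseSd = 0.01, seed = 1L) {
  stage <- match.arg(stage)
  presets <- list(early = list(radius = 5, sd = 0.8, overlap = 0,
                               bg = "flooded"),
                  mid = list(radius = 8, sd = 1.2, overlap = 0.15,
                             bg = "soil"),
                  mature = list(radius = 11, sd = 1.6, overlap = 0.4,
                                bg = "soil"))
  p <- presets[[stage]]
  cfg <- list(imageSize = as.integer(imageSize), stage = stage,
              nPlants = as.integer(nPlants), gridJitter = gridJitter,
              plantRadius = if (is.null(plantRadius)) p$radius else plantRadius,
              radiusSd = if (is.null(radiusSd)) p$sd else radiusSd,
              overlapProb = if (is.null(overlapProb)) p$overlap else overlapProb,
              background = if (is.null(background)) p$bg else
                match.arg(background, c("soil", "flooded")),
              anomalyFraction = anomalyFraction,
              anomalySpec = anomalySpec, noiseSd = noiseSd,
              seed = as.integer(seed))
  stopifnot(cfg$nPlants >= 1L, cfg$anomalyFraction >= 0,
            cfg$anomalyFraction <= 1)
  class(cfg) <- "SceneConfig"
  cfg
}

subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 101 + 1) %% 2147483647)
}

bilinearField <- function(H, W, gc, seed) {
  set.seed(seed)
  m <- matrix(rnorm(gc * gc), gc, gc)
  u <- seq(1, gc, length.out = H)
  v <- seq(1, gc, length.out = W)
  i0 <- pmin(floor(u), gc - 1); j0 <- pmin(floor(v), gc - 1)
  fu <- u - i0; fv <- v - j0
  a <- m[cbind(rep(i0, W), rep(j0, each = H))]
  b <- m[cbind(rep(i0 + 1, W), rep(j0, each = H))]
  cc <- m[cbind(rep(i0, W), rep(j0 + 1, each = H))]
  d <- m[cbind(rep(i0 + 1, W), rep(j0 + 1, each = H))]
  fU <- rep(fu, W); fV <- rep(fv, each = H)
  matrix(a * (1 - fU) * (1 - fV) + b * fU * (1 - fV) +
         cc * (1 - fU) * fV + d * fU * fV, H, W)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic paddy scene with ground truth
#'
#' Deterministic for a fixed seed. Plants are drawn in id order; the
#' ground-truth label map records pre-noise occupancy, with overlaps
#' resolved by draw order (later plant wins contested pixels) — this
#' defines the counting truth at the mature stage.
#'
#' @param cfg a [sceneConfig()].
#' @param id image id (default derived from stage and seed).
#' @return A [SceneTruth-class].
#' @export
generateScene <- function(cfg, id = NULL) {
  stopifnot(inherits(cfg, "SceneConfig"))
  if (is.null(id)) id <- sprintf("scene_%s_s%d", cfg$stage, cfg$seed)
  H <- cfg$imageSize[1]; W <- cfg$imageSize[2]
  n <- cfg$nPlants
  g <- ceiling(sqrt(n))
  spacing <- min(H, W) / g
  if (spacing < 1.6 * cfg$plantRadius) {
    maxN <- floor((min(H, W) / (1.6 * cfg$plantRadius))^2)
    stop("plants cannot fit at the requested density; max feasible ",
         "nPlants for this radius and image size is ", maxN)
  }
  stageIdx <- match(cfg$stage, c("early", "mid", "mature"))

  # placement stream: shared across the stages of a series
  set.seed(subSeed(cfg$seed, 1L))
  cells <- seq_len(n) - 1L
  crow <- (cells %/% g + 0.5) * (H / g)
  ccol <- (cells %% g + 0.5) * (W / g)
  crow <- crow + rnorm(n, 0, cfg$gridJitter)
  ccol <- ccol + rnorm(n, 0, cfg$gridJitter)
  pullU <- runif(n)            # compared against the stage's overlapProb
  pullDir <- sample(c(-1, 1), n, replace = TRUE)
  pulled <- pullU < cfg$overlapProb
  ccol[pulled] <- ccol[pulled] + pullDir[pulled] * 0.35 * spacing

  # identity stream: which plants are anomalous and their stress
  # phenotype (shared across stages: stress persists through the season)
  set.seed(subSeed(cfg$seed, 2L))
  nAnom <- round(cfg$anomalyFraction * n)
  anomIds <- if (nAnom > 0) sort(sample.int(n, nAnom)) else integer(0)
  anomType <- if (nAnom > 0) {
    pool <- rep(c("chlorotic", "stunted", "deformed"),
                length.out = max(3L, nAnom))
    sample(pool)[seq_len(nAnom)]
  } else character(0)

  # appearance stream: stage-specific radii, colors, lobes
  set.seed(subSeed(cfg$seed, 3L + stageIdx))
  # floor keeps the smallest healthy seedling above ~30 px of canopy,
  # clear of the stage-one min-area noise filter
  radius <- pmax(3.2, rnorm(n, cfg$plantRadius, cfg$radiusSd))
  baseCol <- c(0.21, 0.55, 0.17)
  cols <- matrix(rnorm(3 * n, 0, 0.025), n, 3)
  cols <- sweep(cols, 2, baseCol, `+`)
  rough <- numeric(n)
  cols <- clamp01(cols)
  nl <- 4L
  lobeAngle <- matrix(runif(n * nl, 0, pi / nl), n, nl) +
    outer(rep(0, n), (seq_len(nl) - 1) * pi / nl, `+`)
  lobeLen <- matrix(runif(n * nl, 0.85, 1.15), n, nl)
  # phenotype modulation of the configured base anomaly spec; the three
  # phenotypes displace different feature groups, as distinct stressors do
  # chlorosis yellows (base hueShift direction), stunting pales, and
  # deformation darkens toward necrosis -- three stressor signatures
  necrosis <- c(-0.07, -0.21, -0.05)
  typePar <- list(chlorotic = c(hue = 1.0, size = 1.5, rough = 0.4),
                  stunted = c(hue = 0.7, size = 0.45, rough = 0.6),
                  deformed = c(hue = 1.0, size = 1.2, rough = 2.4))
  for (j in seq_along(anomIds)) {
    i <- anomIds[j]
    tp <- typePar[[anomType[j]]]
    hvec <- if (anomType[j] == "deformed") necrosis else
      cfg$anomalySpec$hueShift
    radius[i] <- radius[i] * sqrt(min(1, cfg$anomalySpec$sizeFactor * tp["size"]))
    cols[i, ] <- clamp01(cols[i, ] + tp["hue"] * hvec)
    rough[i] <- cfg$anomalySpec$boundaryRoughness * tp["rough"]
    if (anomType[j] == "deformed")
      lobeLen[i, ] <- lobeLen[i, ] * c(1.9, 0.45, 1.5, 0.5)
  }
  roughPhase <- matrix(runif(n * 2, 0, 2 * pi), n, 2)

  # background
  img <- array(0, c(H, W, 3))
  # tone patches at ~6 px scale: coarse enough for a bimodal background
  # histogram, fine enough that every plant's neighbourhood mixes tones
  field <- bilinearField(H, W, max(8L, as.integer(round(min(H, W) / 6))),
                         subSeed(cfg$seed, 20L + stageIdx))
  set.seed(subSeed(cfg$seed, 30L + stageIdx))
  if (cfg$background == "soil") {
    dry <- c(0.32, 0.30, 0.22); wet <- c(0.30, 0.15, 0.10)
    sel <- field > 0
    for (k in 1:3) img[, , k] <- ifelse(sel, dry[k], wet[k]) +
        rnorm(H * W, 0, 0.02)
  } else {
    water <- c(0.14, 0.17, 0.22); patch <- c(0.25, 0.17, 0.12)
    sel <- field > 0.9
    for (k in 1:3) img[, , k] <- ifelse(sel, patch[k], water[k]) +
        rnorm(H * W, 0, 0.015)
    spark <- runif(H * W) < 0.003   # specular glint on the water
    for (k in 1:3) img[, , k][spark] <- img[, , k][spark] + 0.3
  }

  # plants, in id order; label map records occupancy, later plant wins
  lab <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    ext <- ceiling(radius[i] * 1.45) + 2L
    rr <- max(1L, floor(crow[i]) - ext):min(H, ceiling(crow[i]) + ext)
    cc <- max(1L, floor(ccol[i]) - ext):min(W, ceiling(ccol[i]) + ext)
    if (!length(rr) || !length(cc)) next
    dr <- outer(rr - crow[i], rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - ccol[i])
    q <- matrix(Inf, length(rr), length(cc))
    for (l in seq_len(nl)) {
      th <- lobeAngle[i, l]
      a <- radius[i] * lobeLen[i, l]
      b <- radius[i] * 0.38
      x <- dr * cos(th) + dc * sin(th)
      y <- -dr * sin(th) + dc * cos(th)
      q <- pmin(q, sqrt((x / a)^2 + (y / b)^2))
    }
    q <- pmin(q, sqrt(dr^2 + dc^2) / (radius[i] * 0.45))  # central tuft
    if (rough[i] > 0) {
      ang <- atan2(dc, dr)
      q <- q * (1 + rough[i] * (0.6 * sin(3 * ang + roughPhase[i, 1]) +
                                0.4 * sin(7 * ang + roughPhase[i, 2])))
    }
    alpha <- clamp01((1.04 - q) / 0.12)
    occ <- q <= 1
    shade <- 0.8 + 0.4 * (1 - pmin(q, 1))
    for (k in 1:3) {
      sub <- img[rr, cc, k]
      img[rr, cc, k] <- alpha * cols[i, k] * shade + (1 - alpha) * sub
    }
    lab[rr, cc][occ] <- i
  }

  # sensor noise, added last
  set.seed(subSeed(cfg$seed, 40L + stageIdx))
  img <- clamp01(img + array(rnorm(H * W * 3, 0, cfg$noiseSd), c(H, W, 3)))

  present <- sort(unique(lab[lab > 0L]))
  relab <- match(seq_len(n), present)
  lab[lab > 0L] <- match(lab[lab > 0L], present)
  keptAnom <- which(!is.na(relab[anomIds]))
  new("SceneTruth",
      image = RGBImage(img, scale = "unit", id = id),
      labelMap = lab, counts = length(present),
      anomalyIds = as.integer(relab[anomIds][keptAnom]),
      params = list(config = cfg,
                    centers = cbind(row = crow - 1, col = ccol - 1),
                    radius = radius, plantedAnomalies = anomIds,
                    anomalyTypes = anomType))
}

#' Instance segmentation from ground truth
#'
#' Converts a [SceneTruth-class] label map directly into an
#' [InstanceSegmentation-class] — the harness for running stage two on
#' known (or externally produced) masks, bypassing stage one.
#'
#' @param truth a [SceneTruth-class].
#' @return An [InstanceSegmentation-class] with score 1 per instance.
#' @export
truthSegmentation <- function(truth) {
  lm <- truth@labelMap
  k <- truth@counts
  ctr <- t(vapply(seq_len(k), function(i) {
    idx <- which(lm == i, arr.ind = TRUE)
    c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
  }, numeric(2)))
  info <- data.frame(instance_id = seq_len(k),
                     prompt_row = ctr[, 1], prompt_col = ctr[, 2],
                     score = rep(1, k),
                     area_px = as.integer(tabulate(lm[lm > 0], k)))
  new("InstanceSegmentation", labelMap = lm, instanceInfo = info,
      sourceId = truth@image@id)
}

#' Generate a matched three-stage series
#'
#' Three scenes (early, mid, mature) sharing the planting grid and the
#' anomaly identities, with stage presets applied — the substrate for
#' stage-wise monitoring tests (anomaly persistence across stages).
#'
#' @param seed integer series seed.
#' @param ... overrides passed to [sceneConfig()] for every stage
#'   (anything but `stage` and `seed`).
#' @return named list of three [SceneTruth-class] objects.
#' @export
stageSeries <- function(seed = 1L, ...) {
  stages <- c("early", "mid", "mature")
  out <- lapply(stages, function(st)
    generateScene(sceneConfig(stage = st, seed = seed, ...),
                  id = sprintf("series_s%d_%s", seed, st)))
  names(out) <- stages
  out
}

#' Write a scene to disk
#'
#' PNG image + 16-bit label PNG + truth JSON (counts, anomaly ids, config
#' echo).
#'
#' @param truth a [SceneTruth-class].
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
writeScene <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- truth@image@id
  pImg <- file.path(dir, paste0(id, ".png"))
  pLab <- file.path(dir, paste0(id, "_labels.png"))
  pJson <- file.path(dir, paste0(id, "_truth.json"))
  png::writePNG(truth@image@pixels, pImg)
  writeLabelPNG(truth@labelMap, pLab)
  cfg <- truth@params$config
  jsonlite::write_json(
    list(id = id, counts = truth@counts, anomaly_ids = truth@anomalyIds,
         config = cfg[setdiff(names(cfg), character(0))]),
    pJson, auto_unbox = TRUE, digits = NA)
  invisible(c(pImg, pLab, pJson))
}
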