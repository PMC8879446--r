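# Synthetic multi-domain benchmark. Renders simple geometric shapes with
# random pose and Gaussian pixel noise into grayscale or colour domains,
# optionally with a composite "multiple" class (>= 2 distinct shapes in one
# image), a "normal" distractor class, and configurable negative:positive
# imbalance. Controllable separability is the point, not photographic realism.

SHAPE_NAMES <- c("disc", "bar", "cross", "ring", "wedge", "blob")

CLASS_PALETTE <- list(
  c(1.0, 0.25, 0.25), c(0.25, 1.0, 0.25), c(0.30, 0.45, 1.0),
  c(1.0, 1.0, 0.30), c(1.0, 0.40, 1.0), c(0.40, 1.0, 1.0)
)

#' Specify a synthetic image domain
#'
#' @param name Domain name (used as label prefix and output directory).
#' @param class_shapes Named character vector mapping class name to a shape
#'   primitive (`disc`, `bar`, `cross`, `ring`, `wedge`, `blob`); shapes must
#'   be distinct within a domain.
#' @param channels 1 (grayscale) or 3 (colour).
#' @param image_size Image side length in pixels (>= 8).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise on
#'   the \[0, 1\] intensity scale.
#' @param include_multiple Add a composite `multiple` class whose images
#'   contain >= 2 distinct positive shapes (single-labelled `multiple`).
#' @param include_normal Add a `normal` distractor-texture class.
#' @param imbalance_ratio Normal samples generated per positive sample
#'   (e.g. 10 emulates a 10x negative-heavy screening set).
#' @param items_per_class Images per positive class (and per `multiple`).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name, class_shapes, channels = 1, image_size = 32,
                        noise_sigma = 0.1, include_multiple = FALSE,
                        include_normal = FALSE, imbalance_ratio = 1,
                        items_per_class = 100, seed = 1) {
  stopifnot(length(name) == 1L, is.character(name))
  class_shapes <- unlist(class_shapes)
  if (length(class_shapes) < 1L || is.null(names(class_shapes)) ||
      any(names(class_shapes) == "")) {
    stop_mdcl("class_shapes must be a named vector with >= 1 class", "mdcl_validation_error")
  }
  if (!all(class_shapes %in% SHAPE_NAMES)) {
    stop_mdcl(paste0("unknown shape; use one of: ", paste(SHAPE_NAMES, collapse = ", ")),
              "mdcl_validation_error")
  }
  if (anyDuplicated(class_shapes)) {
    stop_mdcl("shape primitives must be distinct within a domain", "mdcl_validation_error")
  }
  if (!channels %in% c(1, 3)) stop_mdcl("channels must be 1 or 3", "mdcl_validation_error")
  if (image_size < 8) {
    stop_mdcl("image_size must be >= 8 pixels to render shapes", "mdcl_validation_error")
  }
  if (imbalance_ratio < 0) stop_mdcl("imbalance_ratio must be >= 0", "mdcl_validation_error")
  if (include_multiple && length(class_shapes) < 2L) {
    stop_mdcl("a 'multiple' class needs >= 2 positive shapes", "mdcl_validation_error")
  }
  structure(
    list(
      name = name, class_shapes = class_shapes, channels = channels,
      image_size = as.integer(image_size), noise_sigma = noise_sigma,
      include_multiple = include_multiple, include_normal = include_normal,
      imbalance_ratio = imbalance_ratio,
      items_per_class = as.integer(items_per_class), seed = as.integer(seed)
    ),
    class = "domain_spec"
  )
}

# Logical mask for one shape at a random pose; coordinates in [0, 1].
shape_mask <- function(shape, size, cx, cy, s, theta) {
  g <- (seq_len(size) - 0.5) / size
  x <- matrix(g, size, size, byrow = TRUE) - cx
  y <- matrix(g, size, size) - cy
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  r <- sqrt(u^2 + v^2)
  switch(shape,
    disc  = r <= s,
    bar   = abs(u) <= s & abs(v) <= 0.3 * s,
    cross = (abs(u) <= s & abs(v) <= 0.3 * s) | (abs(v) <= s & abs(u) <= 0.3 * s),
    ring  = abs(r - 0.72 * s) <= 0.28 * s,
    wedge = r <= s & ((atan2(v, u) + 2 * pi) %% (2 * pi)) <= 1.9,
    blob  = {
      m <- matrix(FALSE, size, size)
      for (k in 1:4) {
        du <- runif(1, -0.9, 0.9) * s
        dv <- runif(1, -0.9, 0.9) * s
        m <- m | (sqrt((u - du)^2 + (v - dv)^2) <= 0.28 * s)
      }
      m
    },
    stop_mdcl(paste0("unknown shape: ", shape), "mdcl_validation_error")
  )
}

# Moderate pose jitter: enough nuisance variation that the task is not
# template matching, small enough that classes stay learnable from a few
# dozen training images at desk scale.
random_pose <- function() {
  list(cx = runif(1, 0.40, 0.60), cy = runif(1, 0.40, 0.60),
       s = runif(1, 0.20, 0.30), theta = runif(1, -0.35, 0.35))
}

# Render one sample of class `cls` for a domain spec. Returns an image array
# (matrix for 1 channel, h x w x 3 for colour).
render_sample <- function(spec, cls) {
  size <- spec$image_size
  shapes <- spec$class_shapes
  fg <- matrix(0, size, size)                       # shape intensity layer
  col_acc <- array(0, c(size, size, 3))             # colour-weighted layer
  draw <- function(shape, color, gain = 1) {
    p <- random_pose()
    m <- shape_mask(shape, size, p$cx, p$cy, p$s, p$theta)
    fg <<- pmax(fg, m * gain)
    for (k in 1:3) col_acc[, , k] <<- pmax(col_acc[, , k], m * gain * color[k])
  }
  class_color <- function(cls_name) {
    CLASS_PALETTE[[(match(cls_name, names(shapes)) - 1L) %% length(CLASS_PALETTE) + 1L]]
  }
  if (cls == "multiple") {
    k <- sample(2:min(3L, length(shapes)), 1L)
    picks <- sample(names(shapes), k)
    for (p in picks) draw(shapes[[p]], class_color(p))
  } else if (cls == "normal") {
    # faint distractor clutter: two low-contrast thin bars
    for (k in 1:2) draw("bar", c(0.6, 0.6, 0.6), gain = 0.35)
  } else {
    draw(shapes[[cls]], class_color(cls))
  }
  bg <- 0.12
  if (spec$channels == 1L) {
    img <- bg + 0.78 * fg
    img <- img + rnorm(length(img), sd = spec$noise_sigma)
    matrix(pmin(pmax(img, 0), 1), size, size)
  } else {
    img <- bg + 0.78 * col_acc
    img <- img + array(rnorm(length(img), sd = spec$noise_sigma), dim(img))
    array(pmin(pmax(img, 0), 1), dim(img))
  }
}

#' Generate a labelled image set for one domain
#'
#' Deterministic given the spec (including its seed). Positive classes (and
#' `multiple`, when enabled) each receive `items_per_class` images; the
#' `normal` class, when enabled, receives `round(imbalance_ratio * total
#' positives)` images, emulating negative-heavy screening sets.
#'
#' @param spec A [domain_spec()].
#' @return A list with `images` (list of arrays) and `manifest` (tibble with
#'   columns `id`, `domain`, `class`, `label`); labels are domain-prefixed
#'   (`"<domain>/<class>"`).
#' @export
generate_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  classes <- names(spec$class_shapes)
  if (spec$include_multiple) classes <- c(classes, "multiple")
  n_pos_total <- length(classes) * spec$items_per_class
  counts <- setNames(rep(spec$items_per_class, length(classes)), classes)
  if (spec$include_normal) {
    counts <- c(counts, normal = as.integer(round(spec$imbalance_ratio * n_pos_total)))
  }
  withr::with_seed(spec$seed, {
    images <- list(); cls_col <- character(0)
    for (cls in names(counts)) {
      for (i in seq_len(counts[[cls]])) {
        images[[length(images) + 1L]] <- render_sample(spec, cls)
        cls_col <- c(cls_col, cls)
      }
    }
  })
  ids <- sprintf("%s-%s-%04d", spec$name, cls_col, stats::ave(seq_along(cls_col), cls_col, FUN = seq_along))
  list(
    images = images,
    manifest = tibble::tibble(
      id = ids, domain = spec$name, class = cls_col,
      label = paste(spec$name, cls_col, sep = "/")
    )
  )
}

new_dataset <- function(images, labels, ids, domains) {
  list(images = images, labels = labels, ids = ids, domains = domains)
}

dataset_bind <- function(a, b) {
  if (is.null(a)) return(b)
  out <- new_dataset(c(a$images, b$images), c(a$labels, b$labels),
                     c(a$ids, b$ids), c(a$domains, b$domains))
  if (!is.null(a$features) && !is.null(b$features)) {
    out$features <- rbind(a$features, b$features)
  }
  out
}

#' Assemble a class-incremental task sequence from domain specs
#'
#' Generates every referenced domain, applies a per-class stratified
#' train/test split, and slices the result into ordered increments. Labels
#' are domain-prefixed so identically named classes from different domains
#' stay distinct; the global registry lists labels in first-appearance order.
#'
#' @param domain_specs List of [domain_spec()] objects.
#' @param increments Schedule: a list of `list(domain =, classes =)` entries
#'   (classes by their unprefixed in-domain names). Each increment must
#'   introduce at least one new class or a new domain.
#' @param split_fraction Fraction of each class assigned to training
#'   (default 0.2: small train, large test).
#' @param seed Integer seed driving the split (image content is driven by the
#'   per-domain spec seeds).
#' @return An object of class `task_sequence`: a list of increments, each with
#'   `name`, `domain`, `classes` (prefixed), `train` and `test` datasets, plus
#'   a `registry` attribute-style field.
#' @export
generate_benchmark <- function(domain_specs, increments, split_fraction = 0.2, seed = 1) {
  if (length(increments) < 1L) stop_mdcl("need >= 1 increment", "mdcl_validation_error")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_mdcl("split_fraction must be in (0, 1)", "mdcl_validation_error")
  }
  names(domain_specs) <- vapply(domain_specs, `[[`, character(1), "name")
  used <- unique(vapply(increments, `[[`, character(1), "domain"))
  if (!all(used %in% names(domain_specs))) {
    stop_mdcl("schedule references an undeclared domain", "mdcl_validation_error")
  }
  rendered <- lapply(domain_specs[used], generate_domain)

  # per-class stratified split, seeded independently of image content
  split_counter <- 0L
  splits <- lapply(rendered, function(dom) {
    split <- rep("test", nrow(dom$manifest))
    for (cls in unique(dom$manifest$class)) {
      rows <- which(dom$manifest$class == cls)
      n_train <- max(1L, round(split_fraction * length(rows)))
      split_counter <<- split_counter + 1L
      withr::with_seed(derive_seed(seed, split_counter), {
        split[sample(rows, n_train)] <- "train"
      })
    }
    split
  })

  seen_classes <- character(0)
  seen_domains <- character(0)
  incs <- list()
  registry <- character(0)
  for (k in seq_along(increments)) {
    inc <- increments[[k]]
    dom <- inc$domain
    spec <- domain_specs[[dom]]
    declared <- names(spec$class_shapes)
    if (spec$include_multiple) declared <- c(declared, "multiple")
    if (spec$include_normal) declared <- c(declared, "normal")
    if (!all(inc$classes %in% declared)) {
      stop_mdcl(paste0("increment ", k, " references unknown classes in domain ", dom),
                "mdcl_validation_error")
    }
    labels_k <- paste(dom, inc$classes, sep = "/")
    if (!any(!(labels_k %in% seen_classes)) && dom %in% seen_domains) {
      stop_mdcl(paste0("increment ", k, " introduces no new class and no new domain"),
                "mdcl_validation_error")
    }
    man <- rendered[[dom]]$manifest
    sp <- splits[[dom]]
    take <- function(which_split) {
      rows <- which(man$label %in% labels_k & sp == which_split)
      new_dataset(rendered[[dom]]$images[rows], man$label[rows], man$id[rows],
                  man$domain[rows])
    }
    incs[[k]] <- list(
      name = paste0("increment-", k), domain = dom, classes = labels_k,
      train = take("train"), test = take("test")
    )
    registry <- c(registry, setdiff(labels_k, registry))
    seen_classes <- union(seen_classes, labels_k)
    seen_domains <- union(seen_domains, dom)
  }
  structure(
    list(increments = incs, registry = registry, domain_specs = domain_specs,
         split_fraction = split_fraction, seed = seed),
    class = "task_sequence"
  )
}

#' @export
print.task_sequence <- function(x, ...) {
  cat(sprintf("<task_sequence> %d increments, %d classes\n",
              length(x$increments), length(x$registry)))
  for (inc in x$increments) {
    cat(sprintf(
      "  %s [%s]: %s (train %d / test %d)\n", inc$name, inc$domain,
      paste(inc$classes, collapse = ", "),
      length(inc$train$labels), length(inc$test$labels)
    ))
  }
  invisible(x)
}

#' The bundled three-domain continual-learning benchmark
#'
#' Three increments across three domains emulating a cross-modality sequence:
#' a grayscale transmission-scan-like domain, a colour scan domain, and a
#' grayscale retinal-texture-like domain, two classes each. Defaults keep the
#' small-train / large-test regime (20/80 split) and moderate pixel noise so
#' classes are learnable but not trivially linearly separated at one epoch.
#'
#' @param seed Root seed for the train/test split and downstream training.
#' @param items_per_class Images per class per domain.
#' @param image_size Image side length in pixels.
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @param split_fraction Train fraction per class.
#' @return A [generate_benchmark()] task sequence.
#' @export
bundled_benchmark <- function(seed = 1, items_per_class = 100, image_size = 16,
                              noise_sigma = 0.15, split_fraction = 0.2) {
  specs <- list(
    domain_spec("xgray", c(gun = "bar", shuriken = "disc"), channels = 1,
                image_size = image_size, noise_sigma = noise_sigma,
                items_per_class = items_per_class, seed = derive_seed(seed, 101L)),
    domain_spec("xcolor", c(pliers = "wedge", scissors = "ring"), channels = 3,
                image_size = image_size, noise_sigma = noise_sigma,
                items_per_class = items_per_class, seed = derive_seed(seed, 102L)),
    domain_spec("octlike", c(drusen = "blob", edema = "disc"), channels = 1,
                image_size = image_size, noise_sigma = noise_sigma,
                items_per_class = items_per_class, seed = derive_seed(seed, 103L))
  )
  generate_benchmark(
    specs,
    increments = list(
      list(domain = "xgray", classes = c("gun", "shuriken")),
      list(domain = "xcolor", classes = c("pliers", "scissors")),
      list(domain = "octlike", classes = c("drusen", "edema"))
    ),
    split_fraction = split_fraction, seed = seed
  )
}

#' Write a benchmark to disk as PNGs plus a CSV manifest
#'
#' Layout: `<root>/<domain>/<split>/<class>/<id>.png` with a `manifest.csv`
#' at the root recording `id`, `domain`, `class`, `label`, `split`,
#' `increment` and `path`. [read_benchmark()] restores an identical task
#' sequence, so on-disk and in-memory benchmarks flow through the same
#' training code.
#'
#' @param tasks A `task_sequence`.
#' @param root Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_benchmark <- function(tasks, root) {
  stopifnot(inherits(tasks, "task_sequence"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_along(tasks$increments)) {
    inc <- tasks$increments[[k]]
    for (split in c("train", "test")) {
      ds <- inc[[split]]
      for (i in seq_along(ds$ids)) {
        cls <- sub("^[^/]+/", "", ds$labels[i])
        dir_ <- file.path(root, ds$domains[i], split, cls)
        dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
        path <- file.path(dir_, paste0(ds$ids[i], ".png"))
        png::writePNG(ds$images[[i]], path)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = ds$ids[i], domain = ds$domains[i], class = cls,
          label = ds$labels[i], split = split, increment = k,
          path = file.path(ds$domains[i], split, cls, paste0(ds$ids[i], ".png"))
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(root, "manifest.csv"))
  invisible(manifest)
}

#' Read a benchmark written by [write_benchmark()]
#'
#' @param root Directory containing `manifest.csv`.
#' @return A `task_sequence` equivalent to the one written.
#' @export
read_benchmark <- function(root) {
  manifest_path <- file.path(root, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop_mdcl(paste0("no manifest.csv under ", root), "mdcl_validation_error")
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  incs <- list()
  registry <- character(0)
  for (k in sort(unique(man$increment))) {
    sub <- man[man$increment == k, ]
    load_split <- function(which_split) {
      rows <- sub[sub$split == which_split, ]
      images <- lapply(file.path(root, rows$path), function(p) {
        img <- png::readPNG(p)
        if (length(dim(img)) == 3L && dim(img)[3] == 1L) img[, , 1] else img
      })
      new_dataset(images, rows$label, rows$id, rows$domain)
    }
    classes <- unique(sub$label)
    incs[[length(incs) + 1L]] <- list(
      name = paste0("increment-", k), domain = sub$domain[1], classes = classes,
      train = load_split("train"), test = load_split("test")
    )
    registry <- c(registry, setdiff(classes, registry))
  }
  structure(
    list(increments = incs, registry = registry, domain_specs = NULL,
         split_fraction = NA_real_, seed = NA_integer_),
    class = "task_sequence"
  )
}
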