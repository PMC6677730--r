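#' Command-line pipeline dispatcher
#'
#' Implements the `holokit` command line (see `exec/holokit`):
#' `holokit design --config setup.yaml [--csv report.csv]`,
#' `holokit simulate --config setup.yaml --scene scene.yaml --out holo.tif
#' [--background bg.tif] [--seed N]`,
#' `holokit fixtures --out dir [--seed N]`,
#' `holokit reconstruct --input holo.tif [--background bg.tif] --z 5.91e-3
#' --config setup.yaml --out outdir/`,
#' `holokit stack ... --z-min --z-max --planes`,
#' `holokit autofocus ... --z-min --z-max [--steps N]`,
#' `holokit contrast --image recon.tif --rois rois.csv --out report.csv`.
#'
#' Every run writes a JSON sidecar (parameters, seed, package version) next
#' to its outputs, so any artifact is reproducible from its sidecar alone.
#' Inputs are never modified.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `c("design", "--config", "setup.yaml")`.
#' @return Integer exit code, invisibly (0 on success); errors print a
#'   message and return 1.
#' @export
run_pipeline <- function(args) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat(pipeline_usage())
    return(invisible(if (length(args) == 0) 1L else 0L))
  }
  sub <- args[1]
  opts <- parse_cli_args(args[-1])
  handler <- switch(sub,
                    design = cmd_design, simulate = cmd_simulate,
                    fixtures = cmd_fixtures, reconstruct = cmd_reconstruct,
                    stack = cmd_stack, autofocus = cmd_autofocus,
                    contrast = cmd_contrast, NULL)
  if (is.null(handler)) {
    message(sprintf("unknown subcommand '%s'", sub))
    cat(pipeline_usage())
    return(invisible(1L))
  }
  code <- tryCatch({ handler(opts); 0L },
                   error = function(e) {
                     message(sprintf("[%s] error: %s", sub, conditionMessage(e)))
                     1L
                   })
  invisible(code)
}

pipeline_usage <- function() {
  paste0("usage: holokit <design|simulate|fixtures|reconstruct|stack|",
         "autofocus|contrast> [--key value ...]\n")
}

# --key value pairs (plus bare flags) into a named list
parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}

need_opt <- function(opts, key) {
  if (is.null(opts[[key]])) stopf("missing required option --%s", key)
  opts[[key]]
}

# accept "5.91e-3" (metres) or "5.91 mm"
cli_length <- function(x, key) {
  v <- suppressWarnings(as.numeric(x))
  if (!is.na(v)) v else parse_length(x, key)
}

write_sidecar <- function(path, params) {
  params$holokit_version <- as.character(packageVersion("holokit"))
  jsonlite::write_json(params, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

cmd_design <- function(opts) {
  cfg <- load_config(need_opt(opts, "config"))
  rep <- design_report(cfg$setup)
  print(rep)
  if (!is.null(opts$csv)) {
    write.csv(as.data.frame(rep), opts$csv, row.names = FALSE)
    write_sidecar(opts$csv, list(command = "design",
                                 setup = unclass(cfg$setup)))
  }
  invisible(rep)
}

#' Parse a scene description file
#'
#' YAML list under key `objects`; each entry has `kind`, `x`, `y`, `z`
#' (lengths with unit suffixes) plus `radius` or `line_width`, and
#' optionally `amplitude_transmittance`, `dn`, `orientation`.
#'
#' @param path Path to the YAML scene file.
#' @param setup The [optical_setup()] imaging the scene.
#' @return A [scene()].
#' @export
load_scene <- function(path, setup) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$objects)) stopf("scene file has no 'objects' list")
  objs <- lapply(raw$objects, function(o) {
    len <- function(key, default = NULL) {
      if (is.null(o[[key]])) default else parse_length(o[[key]], key)
    }
    scene_object(kind = o$kind,
                 x = len("x", 0), y = len("y", 0), z = len("z"),
                 radius = len("radius"), line_width = len("line_width"),
                 amplitude_transmittance = o$amplitude_transmittance,
                 dn = if (is.null(o$dn)) 0.06 else o$dn,
                 orientation = if (is.null(o$orientation)) "vertical" else o$orientation)
  })
  scene(objs, setup)
}

cmd_simulate <- function(opts) {
  cfg <- load_config(need_opt(opts, "config"))
  out <- need_opt(opts, "out")
  sc <- load_scene(need_opt(opts, "scene"), cfg$setup)
  seed <- as.integer(if (is.null(opts$seed)) cfg$seed else opts$seed)
  rows <- as.integer(if (is.null(opts$rows)) cfg$setup$pixel_count else opts$rows)
  cols <- as.integer(if (is.null(opts$cols)) rows else opts$cols)
  led_like <- isTRUE(opts$led)
  h <- if (led_like) {
    apply_partial_coherence(sc, rows, cols)
  } else {
    simulate_hologram(sc, rows, cols)
  }
  if (!is.null(opts$noise)) {
    h <- add_noise(h, noise_model(photons_per_pixel = as.numeric(opts$noise),
                                  bit_depth = 8, seed = seed))
  }
  top <- max(h$intensity, h$background)
  write_image(h$intensity / top, out, bit_depth = 16)
  if (!is.null(opts$background))
    write_image(h$background / top, opts$background, bit_depth = 16)
  write_sidecar(out, list(command = "simulate", seed = seed,
                          rows = rows, cols = cols, led = led_like,
                          scene = opts$scene, config = opts$config))
  invisible(out)
}

load_hologram_files <- function(opts) {
  cfg <- load_config(need_opt(opts, "config"))
  img <- read_image(need_opt(opts, "input"))
  bg <- if (!is.null(opts$background)) read_image(opts$background) else NULL
  hologram(unclass_img(img), cfg$setup,
           background = if (is.null(bg)) NULL else unclass_img(bg))
}

unclass_img <- function(img) {
  attributes(img) <- attributes(img)[c("dim")]
  img
}

cmd_reconstruct <- function(opts) {
  holo <- load_hologram_files(opts)
  z <- cli_length(need_opt(opts, "z"), "z")
  outdir <- need_opt(opts, "out")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rec <- reconstruct(holo, z, isTRUE(as.logical(opts[["effective-geometry"]])))
  scales <- list()
  for (what in c("amplitude", "phase", "intensity")) {
    img <- rec[[what]]
    # float TIFF stores [0, 1]; keep each image's scale in the sidecar
    if (what == "phase") {
      img <- (img + pi) / (2 * pi)
      scales[[what]] <- list(offset = -pi, scale = 2 * pi)
    } else {
      top <- max(img, 1e-300)
      img <- img / top
      scales[[what]] <- list(offset = 0, scale = top)
    }
    write_image(img, file.path(outdir, paste0(what, ".tif")), bit_depth = 32)
    write_image(normalize_enhance(img), file.path(outdir, paste0(what, ".png")))
  }
  write_sidecar(file.path(outdir, "amplitude.tif"),
                list(command = "reconstruct", z = z, scales = scales,
                     input = opts$input, config = opts$config))
  invisible(rec)
}

cmd_stack <- function(opts) {
  holo <- load_hologram_files(opts)
  z_min <- cli_length(need_opt(opts, "z-min"), "z-min")
  z_max <- cli_length(need_opt(opts, "z-max"), "z-max")
  planes <- as.integer(need_opt(opts, "planes"))
  outdir <- need_opt(opts, "out")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- reconstruct_stack(holo, seq(z_min, z_max, length.out = planes))
  for (i in seq_along(st$z))
    write_image(normalize_enhance(st$planes[[i]]$amplitude),
                file.path(outdir, sprintf("plane_%03d.tif", i)), bit_depth = 16)
  write_sidecar(file.path(outdir, "plane_001.tif"),
                list(command = "stack", z_min = z_min, z_max = z_max,
                     planes = planes, input = opts$input))
  invisible(st)
}

cmd_autofocus <- function(opts) {
  holo <- load_hologram_files(opts)
  z_min <- cli_length(need_opt(opts, "z-min"), "z-min")
  z_max <- cli_length(need_opt(opts, "z-max"), "z-max")
  steps <- as.integer(if (is.null(opts$steps)) 25 else opts$steps)
  z <- autofocus(holo, z_min, z_max, steps)
  cat(sprintf("best focus: %.9g m (%s)\n", z, format_length(z)))
  invisible(z)
}

cmd_contrast <- function(opts) {
  img <- unclass_img(read_image(need_opt(opts, "image")))
  rois <- read.csv(need_opt(opts, "rois"), stringsAsFactors = FALSE)
  out <- need_opt(opts, "out")
  rep <- contrast_report(normalize_enhance(img), rois)
  write.csv(as.data.frame(rep), out, row.names = FALSE)
  write_sidecar(out, list(command = "contrast", image = opts$image,
                          rois = opts$rois))
  last <- last_resolvable(rep)
  if (!is.null(last))
    cat(sprintf("last resolvable: group %d element %d (%.4g lp/mm)\n",
                last$group, last$element, usaf_spatial_frequency(last)))
  else cat("last resolvable: none\n")
  invisible(rep)
}

cmd_fixtures <- function(opts) {
  write_fixtures(need_opt(opts, "out"),
                 seed = as.integer(if (is.null(opts$seed)) 1 else opts$seed))
}

#' Canonical synthetic fixture set
#'
#' Writes the standard small test scenes used throughout the package:
#' a polystyrene-microsphere-like opaque disk (laser-diode-like coherent
#' arm), its LED-like partially coherent counterpart, a red-blood-cell-like
#' phase sphere, a two-depth two-disk scene and a USAF bar panel, each as a
#' 16-bit hologram/background TIFF pair with a matching YAML setup file,
#' plus the USAF ROI table as CSV. All scenes use a desk-scale geometry
#' (256 x 256 detector pixels at 1.12 um pitch) with the source-to-object
#' distance ratio of a typical fringe-magnification instrument.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the sidecars (the scenes are
#'   deterministic; the seed feeds the optional noise stage).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- 256L
  ld <- fixture_setup("ld")
  led <- fixture_setup("led")
  z <- 1.5e-3
  save_pair <- function(h, stem, extra = list()) {
    top <- max(h$intensity, h$background)
    write_image(h$intensity / top, file.path(dir, paste0(stem, ".tif")), 16)
    write_image(h$background / top, file.path(dir, paste0(stem, "_bg.tif")), 16)
    write_sidecar(file.path(dir, paste0(stem, ".tif")),
                  c(list(command = "fixtures", stem = stem, seed = seed,
                         z = z, rows = n, cols = n), extra))
  }
  # PMS-like 3.25 um radius opaque disk, coherent LD arm
  pms <- scene(scene_object("opaque_disk", x = 6e-6, y = -4e-6, z = z,
                            radius = 3.25e-6, amplitude_transmittance = 0), ld)
  save_pair(simulate_hologram(pms, n, n), "pms_ld")
  # same scene, LED-like partially coherent arm
  pms_led <- scene(pms$objects, led)
  save_pair(apply_partial_coherence(pms_led, n, n), "pms_led")
  # RBC-like phase sphere (4 um radius, dn = 0.06)
  rbc <- scene(scene_object("phase_sphere", x = -8e-6, y = 5e-6, z = z,
                            radius = 4e-6, dn = 0.06), ld)
  save_pair(simulate_hologram(rbc, n, n), "rbc_ld")
  # two disks at two depths
  two <- scene(list(
    scene_object("opaque_disk", x = -30e-6, y = 0, z = 1.2e-3, radius = 4e-6),
    scene_object("opaque_disk", x = 35e-6, y = 10e-6, z = 1.9e-3, radius = 5e-6)), ld)
  save_pair(simulate_hologram(two, n, n), "two_depth",
            extra = list(z = c(1.2e-3, 1.9e-3)))
  # USAF panel (group 7), LD arm
  us <- usaf_scene(7L, ld, n, n, z)
  save_pair(simulate_hologram(us$scene, n, n), "usaf_ld")
  write.csv(us$rois, file.path(dir, "usaf_rois.csv"), row.names = FALSE)
  # setup files
  for (arm in c("ld", "led")) {
    cfg <- structure(list(setup = fixture_setup(arm), seed = seed,
                          use_effective_geometry = TRUE,
                          saturation_fraction = 0.002,
                          paths = list()), class = "run_config")
    save_config(cfg, file.path(dir, paste0(arm, "_setup.yaml")))
  }
  invisible(dir)
}

#' Desk-scale study geometries
#'
#' The two instrument arms used by the package's simulations, scaled from a
#' bench instrument to small grids while keeping the object-to-source
#' distance ratio s/f ~ 0.2 of a fringe-magnification design, the 1.12 um
#' camera pitch, and the real illumination parameters: a 405 nm laser-like
#' arm (monochromatic point source) and a 430 nm LED-like arm (15 nm FWHM
#' bandwidth, 15 um pinhole).
#'
#' @param arm `"ld"` or `"led"`.
#' @param pixel_count Grid side (default 256).
#' @param s Object-to-detector distance \[m\] (default 4.25 mm).
#' @param f Source-to-detector distance \[m\] (default 21.5 mm).
#' @return An [optical_setup()].
#' @export
fixture_setup <- function(arm = c("ld", "led"), pixel_count = 256L,
                          s = 4.25e-3, f = 21.5e-3) {
  arm <- match.arg(arm)
  if (arm == "ld")
    optical_setup(405e-9, f, s, pixel_count, 1.12e-6,
                  bandwidth = 0, source_aperture_diameter = 0)
  else
    optical_setup(430e-9, f, s, pixel_count, 1.12e-6,
                  bandwidth = 15e-9, source_aperture_diameter = 15e-6)
}
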