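# Shared fixtures, built in code at test time.

# small convex phantom on an anisotropic grid (fast default for tests)
small_phantom <- function(seed = 1, lobulation = 0, ...) {
  generate_phantom(phantom_spec(shape = c(20L, 72L, 72L),
                                spacing = c(2.5, 0.66, 0.66),
                                semi_axes_mm = c(7, 8, 8),
                                lobulation = lobulation,
                                seed = seed, ...))
}

# preprocess a phantom the way the pipeline does, returning vol+truth
prep_phantom <- function(ph) {
  vol <- normalize_intensity(resample_z_to_pixel_spacing(ph$volume))
  truth <- resample_z_mask(ph$mask)
  list(vol = vol, truth = truth)
}

# tight square seed ROI on the truth's middle slice
middle_seed_roi <- function(truth) {
  zs <- which(apply(truth$data, 1, sum) > 0) - 1L
  z0 <- zs[ceiling(length(zs) / 2)]
  bb <- compute_margins(truth$data[z0 + 1L, , ])$bbox
  sq <- aroiseg:::square_up(bb["x_min"], bb["x_max"] + 1L,
                            bb["y_min"], bb["y_max"] + 1L)
  aroiseg:::clamp_roi(square_roi(z0, sq[1], sq[3], sq[2] - sq[1]),
                      dim(truth$data)[2:3])
}

# write a synthetic DICOM series with pydicom (independent oracle writer);
# z_positions in mm, pixel values int16, optional window tags
write_dicom_series_py <- function(dir, z_positions, rows = 8, cols = 8,
                                  pixel_spacing = c(0.7, 0.7),
                                  slope = 1, intercept = -1024,
                                  window = c(40, 400), seed = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- sprintf('
import pydicom, numpy as np
from pydicom.dataset import Dataset, FileDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
import os
rng = np.random.default_rng(%d)
zs = [%s]
series_uid = generate_uid()
for i, z in enumerate(zs):
    meta = pydicom.dataset.FileMetaDataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = FileDataset(None, {}, file_meta=meta, preamble=b"\\0" * 128)
    ds.Modality = "CT"
    ds.SeriesInstanceUID = series_uid
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.Rows, ds.Columns = %d, %d
    ds.PixelSpacing = ["%g", "%g"]
    ds.ImagePositionPatient = ["0", "0", str(z)]
    ds.ImageOrientationPatient = ["1","0","0","0","1","0"]
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope = "%g"; ds.RescaleIntercept = "%g"
    ds.WindowCenter = "%g"; ds.WindowWidth = "%g"
    arr = (rng.integers(0, 3000, size=(ds.Rows, ds.Columns)) + i).astype(np.int16)
    ds.PixelData = arr.tobytes()
    ds.is_little_endian = True; ds.is_implicit_VR = False
    ds.save_as(os.path.join(r"%s", f"slice{i:03d}.dcm"))
print("OK")
', seed, paste(z_positions, collapse = ", "), rows, cols,
    pixel_spacing[1], pixel_spacing[2], slope, intercept,
    window[1], window[2], dir)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  if (!any(grepl("OK", out))) stop("pydicom fixture writer failed: ",
                                   paste(out, collapse = "\n"))
  invisible(dir)
}

# reference pixel arrays for the pydicom fixture above (recomputed in python)
read_dicom_reference_py <- function(dir) {
  script <- sprintf('
import pydicom, numpy as np, os, json
files = sorted(os.listdir(r"%s"))
out = []
for f in files:
    ds = pydicom.dcmread(os.path.join(r"%s", f))
    arr = ds.pixel_array.astype(float) * float(ds.RescaleSlope) + float(ds.RescaleIntercept)
    out.append({"z": float(ds.ImagePositionPatient[2]), "sum": float(arr.sum()),
                "first": float(arr[0,0])})
print(json.dumps(out))
', dir, dir)
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}
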