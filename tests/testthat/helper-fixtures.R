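# DICOM fixtures are written at test time by pydicom (the independent
# reference implementation for the format), via the python on PATH.

make_dicom_fixture <- function(path, rows = 6, cols = 5,
                               spacing = c("0.2", "0.3"),
                               slope = "2", intercept = "-1",
                               n_frames = 1, with_spacing = TRUE) {
  script <- sprintf('
import pydicom, numpy as np
from pydicom.dataset import FileDataset, FileMetaDataset
fm = FileMetaDataset()
fm.TransferSyntaxUID = pydicom.uid.ExplicitVRLittleEndian
fm.MediaStorageSOPClassUID = pydicom.uid.SecondaryCaptureImageStorage
fm.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
ds = FileDataset(r"%s", {}, file_meta=fm, preamble=b"\\0"*128)
ds.Rows, ds.Columns = %d, %d
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = "MONOCHROME2"
ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
ds.PixelRepresentation = 0
if %s: ds.PixelSpacing = ["%s", "%s"]
ds.RescaleSlope = "%s"; ds.RescaleIntercept = "%s"
if %d > 1: ds.NumberOfFrames = "%d"
arr = np.arange(%d * %d * %d, dtype=np.uint16).reshape(%d, -1)
ds.PixelData = arr.tobytes()
ds.save_as(r"%s", enforce_file_format=True)
', path, rows, cols, if (with_spacing) "True" else "False",
    spacing[1], spacing[2], slope, intercept, n_frames, n_frames,
    n_frames, rows, cols, rows, path)
  status <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) stop("pydicom fixture failed: ", paste(status, collapse = "\n"))
  invisible(path)
}
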