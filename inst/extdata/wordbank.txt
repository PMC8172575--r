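# synthetic word bank for fixture generation (lowercase, alphabetic)
abdominal
acute
adrenal
airway
allergy
anemia
aortic
arterial
artery
asthma
atrial
axillary
bacterial
basal
benign
bilateral
biopsy
bladder
blood
bowel
brain
bronchial
calcium
cardiac
carotid
catheter
cavity
cellular
cerebral
cervical
chest
chronic
clavicle
colon
coronary
cranial
defect
dermal
diastolic
digital
dilated
disease
distal
dorsal
drainage
ductal
duodenal
dysplasia
edema
effusion
ejection
elevated
embolism
enteral
enzyme
escherichia
esophageal
exudate
failure
femoral
fibrosis
fistula
fluid
focal
fracture
frontal
function
fungal
gastric
gland
glucose
graft
granular
gross
growth
hepatic
hernia
humeral
hybrid
hydration
hyperplasia
hypoxia
iliac
infarction
infection
inferior
inflammation
infusion
injury
insulin
internal
jaundice
jejunal
joint
jugular
junction
juvenile
keloid
keratin
ketone
kidney
kinase
knee
lateral
lesion
ligament
lipid
liver
lobar
lumbar
lymph
malignant
marrow
medial
membrane
mitral
motor
mucosal
murmur
muscle
nasal
necrosis
neonatal
nephritis
nerve
neural
nodal
nodule
normal
obstruction
occipital
ocular
optic
orbital
organ
outflow
ovarian
oxygen
palliative
pancreatic
parietal
patellar
pelvic
peptic
pleural
portal
pressure
proximal
pulmonary
quadrant
quadriceps
quantitative
quinine
quotient
radial
rectal
reflux
renal
residual
response
retinal
rhythm
rupture
sacral
saline
segment
sepsis
serum
sinus
spinal
spleen
sternal
stenosis
systolic
tendon
thoracic
thyroid
tissue
tracheal
transplant
trauma
tricuspid
tumor
ulcer
ulnar
umbilical
ureter
urethral
urinary
uterine
valve
vascular
venous
ventral
ventricular
vertebral
vessel
viral
visceral
wall
wasting
wheeze
white
window
wound
wrist
xanthoma
xenograft
xerosis
xiphoid
yeast
yellow
yolk
zygoma
zoster
zonular
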