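# Markups fiducial file version = 4.11
# CoordinateSystem = RAS
# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
vtkMRMLMarkupsFiducialNode_0,0,-10,0,0,0,0,1,1,1,0,PNS,,
vtkMRMLMarkupsFiducialNode_1,20,-15,-10,0,0,0,1,1,1,0,rLT,,
vtkMRMLMarkupsFiducialNode_2,-20,-15,-10,0,0,0,1,1,1,0,lLT,,
vtkMRMLMarkupsFiducialNode_3,12,5,20,0,0,0,1,1,1,0,r_clinoid,,
vtkMRMLMarkupsFiducialNode_4,-12,5,20,0,0,0,1,1,1,0,l_clinoid,,
vtkMRMLMarkupsFiducialNode_5,0,35,-5,0,0,0,1,1,1,0,A,,
vtkMRMLMarkupsFiducialNode_6,0,33,-25,0,0,0,1,1,1,0,B,,
vtkMRMLMarkupsFiducialNode_7,0,38,-8,0,0,0,1,1,1,0,SPr,,
vtkMRMLMarkupsFiducialNode_8,0,36,-22,0,0,0,1,1,1,0,IPr,,
vtkMRMLMarkupsFiducialNode_9,0,-22,12,0,0,0,1,1,1,0,Ba,,
vtkMRMLMarkupsFiducialNode_10,45,-40,5,0,0,0,1,1,1,0,rCo,,
vtkMRMLMarkupsFiducialNode_11,-45,-40,5,0,0,0,1,1,1,0,lCo,,
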